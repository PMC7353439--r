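test_that("noise-free SCM fit recovers the generating (De, N0) almost exactly", {
  spec <- cu_spec()
  g <- gen_dissolution(dissolution_scenario(noise_cv = 0))
  f <- fit_scm(g$series, "porous_shell", spec, C_s = g$truth$C_s)
  expect_true(f$converged)
  expect_lt(abs(f$D_e - 2.39e-11) / 2.39e-11, 1e-6)
  expect_lt(abs(f$N0 - 1.17e12) / 1.17e12, 1e-6)
  expect_lt(f$mse, 1e-20)
  # zero-noise CIs collapse
  expect_lt(f$ci$half_width[["D_e"]] / f$D_e, 1e-5)
  # fitted curve equals the forward model everywhere (objective = oracle)
  prm <- scm_parameters(D_e = f$D_e, C_s = g$truth$C_s, N0 = f$N0)
  fwd <- forward_concentration("porous_shell", spec, prm, g$series$times_s,
                               g$series$volume_m3)
  expect_equal(f$fitted, fwd$conc_kg_m3, tolerance = 1e-12)
})

test_that("doubling the generating N0 doubles fitted plateau and N0, De unchanged", {
  spec <- cu_spec()
  g1 <- gen_dissolution(dissolution_scenario(noise_cv = 0))
  g2 <- gen_dissolution(dissolution_scenario(noise_cv = 0, N0 = 2 * 1.17e12))
  f1 <- fit_scm(g1$series, "porous_shell", spec, C_s = g1$truth$C_s)
  f2 <- fit_scm(g2$series, "porous_shell", spec, C_s = g2$truth$C_s)
  expect_equal(f2$N0 / f1$N0, 2, tolerance = 1e-4)
  expect_equal(f2$D_e, f1$D_e, tolerance = 1e-4)
  expect_equal(max(f2$fitted) / max(f1$fitted), 2, tolerance = 1e-6)
})

test_that("SCM parameter recovery at table scale under 2% noise (scaled down)", {
  # 15-seed version of the 50-seed acceptance run
  spec <- cu_spec()
  De <- c(); N0 <- c()
  for (s in 1:15) {
    g <- gen_dissolution(dissolution_scenario(seed = s))
    f <- fit_scm(g$series, "porous_shell", spec, C_s = g$truth$C_s)
    De <- c(De, f$D_e); N0 <- c(N0, f$N0)
  }
  expect_lt(abs(stats::median(De) - 2.39e-11) / 2.39e-11, 0.1)
  expect_lt(abs(stats::median(N0) - 1.17e12) / 1.17e12, 0.1)
})

test_that("multi-start MSE at the optimum beats every initial point", {
  spec <- cu_spec()
  g <- gen_dissolution(dissolution_scenario(seed = 3))
  f <- fit_scm(g$series, "porous_shell", spec, C_s = g$truth$C_s)
  obs <- g$series$conc_kg_m3
  mse_at <- function(De, N0) {
    prm <- scm_parameters(D_e = De, C_s = g$truth$C_s, N0 = N0)
    fwd <- forward_concentration("porous_shell", spec, prm, g$series$times_s,
                                 g$series$volume_m3)
    mean((fwd$conc_kg_m3 - obs)^2)
  }
  for (fac in 10^seq(-2, 2)) {
    expect_lte(f$mse, mse_at(2.39e-11 * fac, 1.17e12) + 1e-30)
  }
})

test_that("the (De, N0) fit with fixed C_s is identifiable: full-rank Jacobian", {
  spec <- cu_spec()
  g <- gen_dissolution(dissolution_scenario(noise_cv = 0))
  f <- fit_scm(g$series, "porous_shell", spec, C_s = g$truth$C_s)
  J <- shrinkcore:::numeric_jacobian(f$predict_fn, f$par)
  Jlog <- sweep(J, 2, unlist(f$par), `*`)  # scale out the magnitude disparity
  sv <- svd(Jlog)$d
  expect_gt(sv[2] / sv[1], 1e-6)
})

test_that("Nernst-Brunner fit recovers clean first-order curves exactly", {
  g <- gen_dissolution(dissolution_scenario(regime = "nernst_brunner",
                                            noise_cv = 0))
  f <- fit_nernst_brunner(g$series)
  expect_true(f$converged)
  expect_lt(abs(f$k - g$truth$nb_k) / g$truth$nb_k, 1e-8)
  expect_lt(abs(f$C_sat - g$truth$nb_C_sat) / g$truth$nb_C_sat, 1e-8)
  # t -> infinity prediction equals C_sat in the clean model
  pred_inf <- f$C_sat * (1 - exp(-f$k * 1e12))
  expect_equal(pred_inf, f$C_sat, tolerance = 1e-12)
  # geometry supplied: De = k * delta * V / S
  f2 <- fit_nernst_brunner(g$series, S = 2e-3, delta = 2e-7)
  expect_equal(f2$D_e, f2$k * 2e-7 * 1e-3 / 2e-3, tolerance = 1e-12)
})

test_that("Nernst-Brunner C_sat recovery under 2% noise (scaled down)", {
  Cs <- c()
  for (s in 1:15) {
    g <- gen_dissolution(dissolution_scenario(regime = "nernst_brunner",
                                              seed = s))
    f <- fit_nernst_brunner(g$series)
    Cs <- c(Cs, kg_per_m3_to_mg_per_l(f$C_sat))
  }
  expect_lt(abs(stats::median(Cs) - 2.49) / 2.49, 0.1)
})

test_that("bootstrap intervals work and flag the degenerate single-replicate case", {
  g <- gen_dissolution(dissolution_scenario(regime = "nernst_brunner",
                                            seed = 5))
  f <- fit_nernst_brunner(g$series)
  ci_b <- confidence_intervals(f, method = "bootstrap", n_boot = 30, seed = 2)
  expect_false(ci_b$degenerate)
  # bootstrap and covariance intervals agree in order of magnitude
  expect_lt(ci_b$half_width[["C_sat"]] / f$ci$half_width[["C_sat"]], 10)
  expect_gt(ci_b$half_width[["C_sat"]] / f$ci$half_width[["C_sat"]], 0.1)
  expect_warning(ci1 <- confidence_intervals(f, method = "bootstrap",
                                             n_boot = 1, seed = 2),
                 "degenerate")
  expect_true(ci1$degenerate)
})

test_that("degenerate inputs raise fit errors", {
  spec <- cu_spec()
  flat <- dissolution_series(hours_to_seconds(1:6), rep(0, 6), 1e-3, 2.5e-3)
  expect_error(fit_scm(flat, "porous_shell", spec), "degenerate")
  short <- dissolution_series(hours_to_seconds(1:4),
                              mg_per_l_to_kg_per_m3(c(1, 2, 3, 4)), 1e-3, 2.5e-3)
  expect_error(fit_scm(short, "porous_shell", spec), "at least 5")
  expect_error(fit_nernst_brunner(short), "at least 5")
})
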