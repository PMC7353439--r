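test_that("transient window ends at the plateau fraction and drops declining tails", {
  spec <- cu_spec()
  p <- shell_params()
  tau <- tau_complete("porous_shell", spec, p)
  # noise-free shell curve: window end must be the first sample with
  # X >= 0.95 * max(X), verified against the closed form
  t_h <- c(transient_schedule_h("porous_shell", 48, n = 15, X_lo = 0.02,
                                X_hi = 0.999), 96, 150, 240)
  ser <- forward_concentration("porous_shell", spec, p,
                               hours_to_seconds(t_h), 1e-3)
  conv <- conversion_from_concentration(ser)
  w <- extract_transient(conv, plateau_fraction = 0.95)
  end_X <- conv$X[max(w$idx)]
  expect_gte(end_X, 0.95 * max(conv$X))
  expect_true(all(conv$X[seq_len(max(w$idx) - 1)] < 0.95 * max(conv$X)))

  # declining tail (late re-precipitation) is excluded: drops below the
  # running maximum exceed twice the successive-difference noise scale
  Xd <- c(seq(0.1, 0.9, by = 0.1), 0.95, 0.7, 0.6)
  td <- hours_to_seconds(c(seq(4, 36, by = 4), 48, 150, 200))
  convd <- conversion_series(td, Xd)
  wd <- extract_transient(convd)
  expect_true(all(c(11, 12) %in% wd$excluded))
  expect_false(any(c(11, 12) %in% wd$idx))

  expect_error(extract_transient(conversion_series(1:3, c(0, .5, 1))),
               "at least 4")
})

test_that("through-origin linearization is exact on clean same-regime data", {
  spec <- cu_spec()
  for (rg in scm_regimes()) {
    p <- shell_params()
    prm <- scm_parameters(k_s = 1e-9, D_e = 2.39e-11, k_l = 1e-9,
                          C_s = p$C_s, C_l = p$C_s, N0 = 1.17e12)
    tau <- tau_complete(rg, spec, prm)
    t_s <- hours_to_seconds(transient_schedule_h(rg, seconds_to_hours(tau)))
    ser <- forward_concentration(rg, spec, prm, t_s, 1e-3)
    conv <- conversion_from_concentration(ser)
    lin <- linearize_fit(conv, rg)
    expect_equal(lin$adjusted_R2, 1, tolerance = 1e-10)
    expect_equal(lin$slope_inv_tau, 1 / tau, tolerance = 1e-10)
    expect_lt(lin$standard_error, 1e-8)
  }
})

test_that("fitting a wrong regime on clean data scores lower than the true one", {
  spec <- cu_spec()
  p <- shell_params()
  prm <- scm_parameters(k_l = 1e-9, C_l = p$C_s, C_s = p$C_s, N0 = 1.17e12)
  tau <- tau_complete("liquid_film", spec, prm)
  t_s <- hours_to_seconds(transient_schedule_h("liquid_film",
                                               seconds_to_hours(tau)))
  ser <- forward_concentration("liquid_film", spec, prm, t_s, 1e-3)
  conv <- conversion_from_concentration(ser)
  lin_true <- linearize_fit(conv, "liquid_film")
  lin_rxn <- linearize_fit(conv, "core_reaction")
  expect_lt(lin_rxn$adjusted_R2, 1)
  expect_lt(lin_rxn$adjusted_R2, lin_true$adjusted_R2)
})

test_that("slope scales with y and adjusted R2 is invariant to time units", {
  t_s <- hours_to_seconds(c(1, 2, 4, 8, 16, 24))
  X <- c(0.05, 0.1, 0.21, 0.39, 0.72, 0.9)
  conv_h <- conversion_series(t_s, X)
  lin <- linearize_fit(conv_h, "liquid_film")
  # y scaled by c scales the slope by c, leaves adjusted R2 unchanged
  lin_scaled <- linearize_fit(conversion_series(t_s, X / 2), "liquid_film")
  expect_equal(lin_scaled$slope_inv_tau, lin$slope_inv_tau / 2,
               tolerance = 1e-12)
  expect_equal(lin_scaled$adjusted_R2, lin$adjusted_R2, tolerance = 1e-12)
  # time rescaling (s -> h) rescales the slope, not the fit quality
  conv_s <- conversion_series(t_s / 3600, X)
  lin_s <- linearize_fit(conv_s, "liquid_film")
  expect_equal(lin_s$adjusted_R2, lin$adjusted_R2, tolerance = 1e-12)
  expect_equal(lin_s$slope_inv_tau, lin$slope_inv_tau * 3600, tolerance = 1e-9)

  expect_error(linearize_fit(conversion_series(1:4, rep(0, 4)), "liquid_film"),
               "degenerate")
})

test_that("regime selection takes the top adjusted R2 and flags ties", {
  mk <- function(rg, adj) structure(list(regime = rg, slope_inv_tau = 1e-5,
                                         adjusted_R2 = adj, standard_error = 0.01,
                                         n_points = 9L),
                                    class = "regime_linearization")
  # the suspension pattern: film 0.774, shell 0.969, reaction 0.775
  res <- select_regime(list(liquid_film = mk("liquid_film", 0.774),
                            porous_shell = mk("porous_shell", 0.969),
                            core_reaction = mk("core_reaction", 0.775)))
  expect_identical(res$selected, "porous_shell")
  expect_false(res$tie_flag)
  # the membrane pattern: 0.902 / 0.999 / 0.904
  res2 <- select_regime(list(liquid_film = mk("liquid_film", 0.902),
                             porous_shell = mk("porous_shell", 0.999),
                             core_reaction = mk("core_reaction", 0.904)))
  expect_identical(res2$selected, "porous_shell")
  # exact ties: flagged, first in enumeration order wins deterministically
  res3 <- select_regime(list(liquid_film = mk("liquid_film", 0.9),
                             porous_shell = mk("porous_shell", 0.9),
                             core_reaction = mk("core_reaction", 0.9)))
  expect_true(res3$tie_flag)
  expect_identical(res3$selected, "liquid_film")
})

test_that("fitted slope converges to 1/tau as noise vanishes", {
  spec <- cu_spec()
  tau_h <- 48
  t_h <- transient_schedule_h("porous_shell", tau_h)
  sc <- dissolution_scenario(schedule_h = t_h, noise_cv = 1e-4, seed = 11)
  g <- gen_dissolution(sc)
  conv <- conversion_from_concentration(g$series)
  lin <- linearize_fit(conv, "porous_shell")
  expect_lt(abs(lin$slope_inv_tau - 1 / hours_to_seconds(tau_h)) *
              hours_to_seconds(tau_h), 1e-3)
})

test_that("regime recovery is reliable at 1% noise with good transient coverage", {
  # scaled-down power check (20 series per regime); the full 100-series
  # version runs in the acceptance suite
  for (rg in scm_regimes()) {
    t_h <- transient_schedule_h(rg, 48)
    correct <- 0L
    for (s in 1:20) {
      g <- gen_dissolution(dissolution_scenario(
        regime = rg, constant = 2.39e-11, tau_complete_h = 48,
        schedule_h = t_h, noise_cv = 0.01, seed = s))
      sel <- determine_step(conversion_from_concentration(g$series))$selected
      correct <- correct + (sel == rg)
    }
    expect_gte(correct, 19L)
  }
})
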