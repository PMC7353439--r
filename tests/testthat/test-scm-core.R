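test_that("conversion laws satisfy their closed-form identities", {
  for (rg in scm_regimes()) {
    expect_identical(g_regime(0, rg), 0)
    expect_equal(g_regime(1, rg), 1, tolerance = 1e-12)
    X <- seq(0, 1, length.out = 1000)
    g <- g_regime(X, rg)
    expect_true(all(diff(g) > 0))            # strictly increasing
    expect_true(all(g >= 0 & g <= 1))
    # invert_g o g = identity
    expect_equal(invert_g(g, rg), X, tolerance = 1e-10)
    # g o invert_g = identity
    s <- seq(0, 1, length.out = 1000)
    expect_equal(g_regime(invert_g(s, rg), rg), s, tolerance = 1e-10)
  }
  # exact substitution u = (1-X)^(1/3) = 0.5 at X = 0.875:
  # shell: 1 - 3*0.25 + 2*0.125 = 0.5; reaction: 1 - 0.5 = 0.5
  expect_equal(g_regime(0.875, "porous_shell"), 0.5, tolerance = 1e-14)
  expect_equal(g_regime(0.875, "core_reaction"), 0.5, tolerance = 1e-14)
  expect_equal(invert_g(0.5, "porous_shell"), 0.875, tolerance = 1e-10)
  expect_equal(invert_g(0.5, "core_reaction"), 0.875, tolerance = 1e-12)
  expect_error(g_regime(1.5, "liquid_film"), "\\[0, 1\\]")
  expect_error(invert_g(-0.2, "porous_shell"), "\\[0, 1\\]")
  expect_error(g_regime(0.5, "mixed"), "regime")
})

test_that("shell control is slowest early: g_shell <= g_reaction <= g_film up to the crossing", {
  # g_shell - g_reaction = -u(2u-1)(u-1) with u = (1-X)^(1/3): shell lies
  # below reaction exactly while u >= 1/2, i.e. X <= 0.875, where the two
  # curves cross (both equal 0.5); reaction <= film holds on all of (0,1)
  X <- seq(0.001, 0.875, length.out = 500)
  g_sh <- g_regime(X, "porous_shell")
  g_rx <- g_regime(X, "core_reaction")
  expect_true(all(g_sh <= g_rx + 1e-14))
  X_all <- seq(0.001, 0.999, length.out = 500)
  expect_true(all(g_regime(X_all, "core_reaction") <=
                    g_regime(X_all, "liquid_film") + 1e-14))
  # beyond the crossing the order reverses
  X_late <- seq(0.876, 0.999, length.out = 100)
  expect_true(all(g_regime(X_late, "porous_shell") >=
                    g_regime(X_late, "core_reaction") - 1e-14))
})

test_that("characteristic times follow their formulas and scalings", {
  spec <- particle_spec("Cu-NPs", radius_m = 12.5e-9, density_kg_m3 = 8960)
  p <- scm_parameters(D_e = 2.39e-11, C_s = 1)
  # independent hand evaluation of rho*R^2/(6*De*Cs)
  expect_equal(tau_complete("porous_shell", spec, p),
               8960 * (12.5e-9)^2 / (6 * 2.39e-11 * 1), tolerance = 1e-12)

  # tau proportional to 1/De and to R^2
  p2 <- scm_parameters(D_e = 2 * 2.39e-11, C_s = 1)
  expect_equal(tau_complete("porous_shell", spec, p2),
               tau_complete("porous_shell", spec, p) / 2, tolerance = 1e-12)
  spec2 <- particle_spec("Cu-NPs", radius_m = 25e-9, density_kg_m3 = 8960)
  expect_equal(tau_complete("porous_shell", spec2, p),
               4 * tau_complete("porous_shell", spec, p), tolerance = 1e-12)

  # dimensional consistency: R -> aR with De -> a^2 De leaves tau invariant
  a <- 3.7
  spec_a <- particle_spec("x", radius_m = a * 12.5e-9, density_kg_m3 = 8960)
  p_a <- scm_parameters(D_e = a^2 * 2.39e-11, C_s = 1)
  expect_equal(tau_complete("porous_shell", spec_a, p_a),
               tau_complete("porous_shell", spec, p), tolerance = 1e-12)

  # the other two regimes
  pk <- scm_parameters(k_s = 1e-9, k_l = 1e-9, C_s = 2, C_l = 5)
  expect_equal(tau_complete("core_reaction", spec, pk),
               8960 * 12.5e-9 / (1e-9 * 2), tolerance = 1e-12)
  expect_equal(tau_complete("liquid_film", spec, pk),
               8960 * 12.5e-9 / (3 * 1e-9 * 5), tolerance = 1e-12)
  expect_error(tau_complete("porous_shell", spec, scm_parameters(D_e = 0, C_s = 1)),
               "requires")
})

test_that("conversion maps dissolved mass over initial mass, with clipping flag", {
  # 1 L, 2.5 g copper, 100 mg/L dissolved -> X = 0.1/2.5 = 0.04
  ser <- dissolution_series(hours_to_seconds(c(1, 24, 48)),
                            mg_per_l_to_kg_per_m3(c(10, 50, 100)),
                            volume_m3 = 1e-3, initial_copper_kg = 2.5e-3)
  conv <- conversion_from_concentration(ser)
  expect_equal(conv$X, c(0.004, 0.02, 0.04), tolerance = 1e-12)
  expect_false(conv$inconsistent)

  # zero dissolution and full conversion endpoints
  ser0 <- dissolution_series(c(0, 3600), c(0, 0), 1e-3, 2.5e-3)
  expect_equal(conversion_from_concentration(ser0)$X, c(0, 0))
  serf <- dissolution_series(c(0, 3600), c(0, 2.5), 1e-3, 2.5e-3)
  expect_equal(conversion_from_concentration(serf)$X[2], 1)

  # over-unity raw conversion is clipped and flagged
  serov <- dissolution_series(c(0, 3600), c(0, 2.6), 1e-3, 2.5e-3,
                              check_mass = FALSE)
  convov <- conversion_from_concentration(serov)
  expect_true(convov$inconsistent)
  expect_equal(max(convov$X), 1)

  expect_error(dissolution_series(c(0, 3600), c(0, 1), 1e-3, 0),
               "initial_copper_kg")
})

test_that("forward concentration starts at zero, plateaus at N0*m_p*w/V, conserves mass", {
  spec <- cu_spec()
  p <- shell_params()
  tau <- tau_complete("porous_shell", spec, p)
  times <- c(1e-9, tau / 4, tau / 2, tau, 2 * tau)
  ser <- forward_concentration("porous_shell", spec, p, times, 1e-3)
  # hand-computed plateau: N0 * rho * (4/3) pi R^3 * w / V
  plateau <- 1.17e12 * 8960 * (4 / 3) * pi * (12.5e-9)^3 * 1 / 1e-3
  expect_equal(ser$conc_kg_m3[4], plateau, tolerance = 1e-12)
  expect_equal(ser$conc_kg_m3[5], plateau, tolerance = 1e-12)
  expect_lt(ser$conc_kg_m3[1], 1e-3 * plateau)
  expect_true(all(diff(ser$conc_kg_m3) >= 0))
  expect_true(all(ser$conc_kg_m3 * ser$volume_m3 <=
                    p$N0 * particle_mass(spec) * 1 + 1e-20))
  # clean shell curve at t = tau/2: X = 0.875 of the plateau
  ser2 <- forward_concentration("porous_shell", spec, p, tau / 2, 1e-3)
  expect_equal(ser2$conc_kg_m3, 0.875 * plateau, tolerance = 1e-10)
})

test_that("forward concentration is monotone and mass-conserving over random parameters", {
  set.seed(42)
  for (i in 1:1000) {
    rg <- sample(scm_regimes(), 1)
    spec <- particle_spec("x", radius_m = 10^stats::runif(1, -9, -7),
                          density_kg_m3 = stats::runif(1, 2000, 12000),
                          copper_mass_fraction = stats::runif(1, 0.3, 1))
    p <- scm_parameters(k_s = 10^stats::runif(1, -12, -6),
                        D_e = 10^stats::runif(1, -13, -9),
                        k_l = 10^stats::runif(1, -12, -6),
                        C_s = 10^stats::runif(1, -8, 0),
                        C_l = 10^stats::runif(1, -8, 0),
                        N0 = 10^stats::runif(1, 8, 14))
    tau <- tau_complete(rg, spec, p)
    times <- sort(stats::runif(8, 0.01, 2)) * tau
    ser <- forward_concentration(rg, spec, p, times, 1e-3)
    expect_true(all(diff(ser$conc_kg_m3) >= -1e-15))
    cap <- p$N0 * particle_mass(spec) * spec$copper_mass_fraction
    expect_true(all(ser$conc_kg_m3 * ser$volume_m3 <= cap * (1 + 1e-12)))
  }
})

test_that("particle count from mass is linear and matches hand arithmetic", {
  spec <- cu_spec()
  n <- particle_count_from_mass(2.5e-3, spec)
  # 2.5 g / (8960 * (4/3) pi (12.5e-9)^3) ~ 3.4e16, far above the apparent
  # fitted count (consistent with agglomeration)
  expect_equal(n, 2.5e-3 / (8960 * (4 / 3) * pi * (12.5e-9)^3),
               tolerance = 1e-12)
  expect_gt(n / 1.17e12, 1e3)
  expect_equal(particle_count_from_mass(5e-3, spec), 2 * n, tolerance = 1e-12)
  spec2 <- particle_spec("x", 25e-9, 8960)
  expect_equal(particle_count_from_mass(2.5e-3, spec2), n / 8, tolerance = 1e-12)
})

test_that("particle_spec and scm_parameters validate their invariants", {
  expect_error(particle_spec("x", -1e-9, 8960), "radius_m")
  expect_error(particle_spec("x", 1e-9, 8960, copper_mass_fraction = 0),
               "copper_mass_fraction")
  expect_error(particle_spec("x", 1e-9, 8960, copper_mass_fraction = 1.2),
               "copper_mass_fraction")
  expect_error(scm_parameters(D_e = -1), "D_e")
  expect_error(dissolution_series(c(0, 0), c(0, 0), 1e-3, 1e-3),
               "strictly increasing")
  expect_error(dissolution_series(c(0, 1), c(-1, 0), 1e-3, 1e-3), ">= 0")
  expect_error(dissolution_series(c(0, 1), c(0, 5), 1e-3, 1e-3),
               "exceeds the initial copper mass")
})
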