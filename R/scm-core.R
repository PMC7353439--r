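# Shrinking core model: conversion laws, characteristic times, forward model.
#
# A spherical particle of initial radius R dissolves from the outside in,
# leaving a porous product shell around a shrinking unreacted core of radius
# r_NP(t). Conversion is the reacted volume fraction X = 1 - (r_NP/R)^3.
# Under a single rate-limiting resistance the conversion obeys
#   t / tau = g(X)
# with a regime-specific g and a characteristic time tau for complete
# conversion (X = 1 at t = tau).

#' Candidate rate-limiting regimes
#'
#' The three serial resistances that can control dissolution: diffusion
#' through the liquid film around the particle, diffusion through the porous
#' product shell, and the chemical reaction at the core surface. `"mixed"` is
#' accepted only by the numerical oracle ([ode_oracle()]).
#'
#' @return character vector of the three single-resistance regime names.
#' @export
scm_regimes <- function() c("liquid_film", "porous_shell", "core_reaction")

match_regime <- function(regime, allow_mixed = FALSE) {
  choices <- c(scm_regimes(), if (allow_mixed) "mixed")
  if (!is.character(regime) || length(regime) != 1L || !regime %in% choices)
    stop_input("'regime' must be one of: %s", paste(choices, collapse = ", "))
  regime
}

#' Kinetic and transport parameters of the shrinking core model
#'
#' Collects the constants of the three transport/reaction steps. Only the
#' constants relevant to the regime in use need to be supplied.
#'
#' @param k_s surface-reaction rate constant (m/s).
#' @param D_e effective diffusivity through the porous shell (m\eqn{^2}/s).
#' @param k_l liquid-film mass-transfer coefficient (m/s).
#' @param C_s cupric-ion concentration at the core surface (saturation),
#'   kg/m\eqn{^3}.
#' @param C_shell cupric-ion concentration at the outer shell boundary,
#'   kg/m\eqn{^3}.
#' @param C_l bulk-liquid cupric-ion concentration, kg/m\eqn{^3}.
#' @param N0 apparent number of dissolving particles (dimensionless count).
#' @return an object of class `scm_parameters`.
#' @export
scm_parameters <- function(k_s = NA_real_, D_e = NA_real_, k_l = NA_real_,
                           C_s = NA_real_, C_shell = NA_real_, C_l = NA_real_,
                           N0 = NA_real_) {
  p <- list(k_s = k_s, D_e = D_e, k_l = k_l, C_s = C_s,
            C_shell = C_shell, C_l = C_l, N0 = N0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop_input("'%s' must be a single number or NA", nm)
    if (is.finite(v) && v < 0)
      stop_input("'%s' must be >= 0 (got %g)", nm, v)
  }
  structure(p, class = "scm_parameters")
}

#' Conversion law g(X) of a single-resistance regime
#'
#' The dimensionless time \eqn{t/\tau = g(X)} for each rate-limiting step:
#' \describe{
#'   \item{core_reaction}{\eqn{g(X) = 1 - (1-X)^{1/3}}}
#'   \item{porous_shell}{\eqn{g(X) = 1 - 3(1-X)^{2/3} + 2(1-X)}}
#'   \item{liquid_film}{\eqn{g(X) = X}}
#' }
#' All three satisfy \eqn{g(0)=0}, \eqn{g(1)=1} and are strictly increasing
#' on \eqn{[0,1]}.
#'
#' @param X conversion, numeric vector in \eqn{[0,1]}.
#' @param regime one of [scm_regimes()].
#' @return \eqn{g(X)}, same length as `X`.
#' @export
g_regime <- function(X, regime) {
  regime <- match_regime(regime)
  if (!is.numeric(X)) stop_input("'X' must be numeric")
  if (any(!is.finite(X)) || any(X < -1e-12) || any(X > 1 + 1e-12))
    stop_input("conversion 'X' must lie in [0, 1]")
  X <- pmin(pmax(X, 0), 1)
  u <- (1 - X)^(1 / 3)  # dimensionless core radius r_NP / R
  switch(regime,
    liquid_film   = X,
    porous_shell  = 1 - 3 * u^2 + 2 * u^3,
    core_reaction = 1 - u
  )
}

#' Invert a conversion law
#'
#' Solves \eqn{g(X) = s} for \eqn{X} given dimensionless time
#' \eqn{s = t/\tau \in [0,1]}. Closed form for liquid film (\eqn{X = s}) and
#' core reaction (\eqn{X = 1-(1-s)^3}); for the porous shell the cubic
#' \eqn{1 - 3u^2 + 2u^3 = s} in \eqn{u = (1-X)^{1/3}} is solved by bisection
#' on \eqn{[0,1]}, where it is monotone.
#'
#' @param s dimensionless time \eqn{t/\tau}, numeric vector in \eqn{[0,1]}.
#' @param regime one of [scm_regimes()].
#' @return conversion \eqn{X} with `g_regime(X, regime) == s` to 1e-10.
#' @export
invert_g <- function(s, regime) {
  regime <- match_regime(regime)
  if (!is.numeric(s)) stop_input("'s' must be numeric")
  if (any(!is.finite(s)) || any(s < -1e-12) || any(s > 1 + 1e-12))
    stop_input("dimensionless time 's' must lie in [0, 1]")
  s <- pmin(pmax(s, 0), 1)
  switch(regime,
    liquid_film   = s,
    core_reaction = 1 - (1 - s)^3,
    porous_shell  = {
      # g(u) = 1 - 3u^2 + 2u^3 decreases from 1 (u=0) to 0 (u=1);
      # bisect to below 1e-12 in u, then X = 1 - u^3.
      lo <- rep(0, length(s))
      hi <- rep(1, length(s))
      for (i in seq_len(64)) {
        mid <- (lo + hi) / 2
        gmid <- 1 - 3 * mid^2 + 2 * mid^3
        take <- gmid > s
        lo[take] <- mid[take]
        hi[!take] <- mid[!take]
      }
      1 - ((lo + hi) / 2)^3
    }
  )
}

#' Characteristic time for complete conversion
#'
#' The time \eqn{\tau} at which the core is fully consumed under a single
#' controlling resistance:
#' \describe{
#'   \item{core_reaction}{\eqn{\tau_s = \rho_{NP} R / (k_s C_s)}}
#'   \item{porous_shell}{\eqn{\tau_{shell} = \rho_{NP} R^2 / (6 D_e C_s)}}
#'   \item{liquid_film}{\eqn{\tau_l = \rho_{NP} R / (3 k_l C_l)}}
#' }
#'
#' @param regime one of [scm_regimes()].
#' @param spec a [particle_spec()].
#' @param params an [scm_parameters()] supplying the regime's constant and
#'   driving concentration.
#' @return characteristic time in seconds.
#' @export
tau_complete <- function(regime, spec, params) {
  regime <- match_regime(regime)
  stopifnot(inherits(spec, "particle_spec"), inherits(params, "scm_parameters"))
  need <- switch(regime,
    core_reaction = c("k_s", "C_s"),
    porous_shell  = c("D_e", "C_s"),
    liquid_film   = c("k_l", "C_l")
  )
  for (nm in need) {
    v <- params[[nm]]
    if (!is.finite(v) || v <= 0)
      stop_input("tau(%s) requires '%s' > 0 (got %s)", regime, nm, format(v))
  }
  rho <- spec$density_kg_m3
  R <- spec$radius_m
  switch(regime,
    core_reaction = rho * R / (params$k_s * params$C_s),
    porous_shell  = rho * R^2 / (6 * params$D_e * params$C_s),
    liquid_film   = rho * R / (3 * params$k_l * params$C_l)
  )
}

#' Measured dissolved-ion time series
#'
#' Container for an ion-release experiment: sampling times, dissolved
#' Cu\eqn{^{2+}} concentration, the solution volume and the initial copper
#' mass loaded. Internally SI; use [read_dissolution_csv()] for h / mg/L
#' input.
#'
#' @param times_s sampling times in seconds, strictly increasing, \eqn{\ge 0}.
#' @param conc_kg_m3 dissolved copper concentration in kg/m\eqn{^3},
#'   \eqn{\ge 0}.
#' @param volume_m3 solution volume in m\eqn{^3} (> 0).
#' @param initial_copper_kg initial copper mass in kg (> 0).
#' @param check_mass if `TRUE` (default), error when dissolved mass exceeds
#'   the initial copper mass by more than 0.1% beyond measurement rounding.
#' @return an object of class `dissolution_series`.
#' @export
dissolution_series <- function(times_s, conc_kg_m3, volume_m3,
                               initial_copper_kg, check_mass = TRUE) {
  if (!is.numeric(times_s) || !is.numeric(conc_kg_m3))
    stop_input("times and concentrations must be numeric")
  if (length(times_s) != length(conc_kg_m3))
    stop_input("times and concentrations must have equal length")
  if (any(!is.finite(times_s)) || any(!is.finite(conc_kg_m3)))
    stop_input("times and concentrations must be finite")
  if (any(times_s < 0)) stop_input("times must be >= 0")
  if (any(diff(times_s) <= 0)) stop_input("times must be strictly increasing")
  if (any(conc_kg_m3 < 0)) stop_input("concentrations must be >= 0")
  check_number(volume_m3, "volume_m3", positive = TRUE)
  check_number(initial_copper_kg, "initial_copper_kg", positive = TRUE)
  if (check_mass &&
      any(conc_kg_m3 * volume_m3 > initial_copper_kg * (1 + 1e-3)))
    stop_input("dissolved mass exceeds the initial copper mass")
  structure(
    list(times_s = as.numeric(times_s), conc_kg_m3 = as.numeric(conc_kg_m3),
         volume_m3 = volume_m3, initial_copper_kg = initial_copper_kg),
    class = "dissolution_series"
  )
}

#' @export
print.dissolution_series <- function(x, ...) {
  cat(sprintf(
    "<dissolution_series> %d points, t = %.3g..%.3g h, C max = %.4g mg/L, V = %g L, m0 = %g g\n",
    length(x$times_s), seconds_to_hours(min(x$times_s)),
    seconds_to_hours(max(x$times_s)),
    kg_per_m3_to_mg_per_l(max(x$conc_kg_m3)),
    x$volume_m3 * 1e3, x$initial_copper_kg * 1e3))
  invisible(x)
}

#' Dimensionless conversion time series
#'
#' @param times_s times in seconds.
#' @param X conversion in \eqn{[0,1]}.
#' @param inconsistent logical flag: `TRUE` when the raw conversion exceeded
#'   1 before clipping (data inconsistency recorded by
#'   [conversion_from_concentration()]).
#' @return an object of class `conversion_series`.
#' @export
conversion_series <- function(times_s, X, inconsistent = FALSE) {
  if (length(times_s) != length(X)) stop_input("length mismatch")
  if (any(diff(times_s) <= 0)) stop_input("times must be strictly increasing")
  if (any(X < 0) || any(X > 1)) stop_input("X must lie in [0, 1]")
  structure(list(times_s = as.numeric(times_s), X = as.numeric(X),
                 inconsistent = isTRUE(inconsistent)),
            class = "conversion_series")
}

#' Conversion from measured concentration
#'
#' Maps a dissolved-ion series to dimensionless conversion
#' \eqn{X(t) = C(t)\,V / m_0}, the dissolved copper mass over the initial
#' copper mass. Values exceeding 1 by more than `tol` (relative) are clipped
#' and flagged in the result's `inconsistent` field.
#'
#' @param series a [dissolution_series()].
#' @param spec a [particle_spec()] (carried for provenance; the mapping
#'   itself is mass-based).
#' @param tol relative tolerance above 1 before flagging inconsistency.
#' @return a [conversion_series()].
#' @export
conversion_from_concentration <- function(series, spec = NULL, tol = 1e-6) {
  stopifnot(inherits(series, "dissolution_series"))
  if (series$initial_copper_kg <= 0)
    stop_input("initial copper mass must be > 0")
  X_raw <- series$conc_kg_m3 * series$volume_m3 / series$initial_copper_kg
  # measurement noise can push X past 1; record the inconsistency in the
  # result metadata and clip
  inconsistent <- any(X_raw > 1 + tol)
  conversion_series(series$times_s, pmin(pmax(X_raw, 0), 1),
                    inconsistent = inconsistent)
}

#' Forward-simulated concentration curve
#'
#' The clean shrinking-core prediction for dissolved copper:
#' \deqn{C(t) = N_0\, \rho_{NP} \tfrac{4}{3}\pi R^3\, w_{Cu}\, X(t/\tau) / V,}
#' with \eqn{X(s) = } [invert_g()]`(min(s, 1), regime)`. The curve is monotone
#' non-decreasing and reaches its plateau \eqn{N_0 m_p w_{Cu} / V} at
#' \eqn{t \ge \tau}.
#'
#' @param regime one of [scm_regimes()].
#' @param spec a [particle_spec()].
#' @param params an [scm_parameters()] with `N0` and the regime's constants.
#' @param times_s sampling times in seconds, sorted, \eqn{\ge 0}.
#' @param volume_m3 solution volume in m\eqn{^3}.
#' @param initial_copper_kg conversion basis for the returned series; default
#'   is the releasable copper mass \eqn{N_0 m_p w_{Cu}}.
#' @return a [dissolution_series()].
#' @export
forward_concentration <- function(regime, spec, params, times_s, volume_m3,
                                  initial_copper_kg = NULL) {
  regime <- match_regime(regime)
  stopifnot(inherits(spec, "particle_spec"), inherits(params, "scm_parameters"))
  check_number(volume_m3, "volume_m3", positive = TRUE)
  if (!is.finite(params$N0) || params$N0 <= 0)
    stop_input("'N0' must be > 0 for forward simulation")
  if (any(times_s < 0) || any(diff(times_s) <= 0))
    stop_input("'times_s' must be sorted, strictly increasing and >= 0")
  tau <- tau_complete(regime, spec, params)
  s <- pmin(times_s / tau, 1)
  X <- invert_g(s, regime)
  releasable <- params$N0 * particle_mass(spec) * spec$copper_mass_fraction
  if (is.null(initial_copper_kg)) initial_copper_kg <- releasable
  dissolution_series(times_s, releasable * X / volume_m3, volume_m3,
                     initial_copper_kg)
}
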