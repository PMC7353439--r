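# Rate-limiting-step determination: linearize the transient conversion data
# under each candidate regime as y = (1/tau) t through the origin, score each
# fit with the no-intercept adjusted R^2, and select the best.

#' Extract the transient window of a conversion series
#'
#' The linearizations only apply to the transient phase, before the curve
#' settles on its plateau. The window runs from the first sample to the first
#' time the conversion reaches `plateau_fraction` of the maximum observed
#' conversion. With `enforce_monotone = TRUE`, trailing points that fall
#' below the running maximum by more than twice the estimated noise SD
#' (median absolute successive difference, scaled to an SD) are excluded
#' first — this handles the late decline seen for elemental Cu nanoparticles,
#' whose dissolved concentration drops after ~150 h as cupric ions
#' re-precipitate.
#'
#' @param conv a [conversion_series()] with at least 4 points.
#' @param plateau_fraction fraction of the maximum observed conversion at
#'   which the transient is deemed over (default 0.95).
#' @param enforce_monotone drop declining-tail points before windowing.
#' @return a `transient_window` list: `idx` (integer indices into `conv`),
#'   `plateau_fraction`, `excluded` (indices dropped by the monotone filter),
#'   `noise_sd` (the tolerance scale used).
#' @export
extract_transient <- function(conv, plateau_fraction = 0.95,
                              enforce_monotone = TRUE) {
  stopifnot(inherits(conv, "conversion_series"))
  if (length(conv$X) < 4L) stop_input("need at least 4 points")
  check_number(plateau_fraction, "plateau_fraction", positive = TRUE)
  if (plateau_fraction > 1) stop_input("'plateau_fraction' must be <= 1")

  X <- conv$X
  keep <- rep(TRUE, length(X))
  noise_sd <- 0
  if (enforce_monotone) {
    # Robust noise scale from successive differences: for iid noise,
    # sd(diff) = sqrt(2) * sd, and MAD/0.6745 estimates an SD.
    d <- diff(X)
    noise_sd <- stats::median(abs(d)) / (0.6745 * sqrt(2))
    keep <- X >= cummax(X) - 2 * noise_sd
  }
  excluded <- which(!keep)
  idx_kept <- which(keep)
  Xk <- X[idx_kept]
  end <- idx_kept[which(Xk >= plateau_fraction * max(Xk))[1]]
  idx <- idx_kept[idx_kept <= end]
  if (length(idx) < 3L)
    stop_input("fewer than 3 points survive the transient window")
  structure(list(idx = idx, plateau_fraction = plateau_fraction,
                 excluded = excluded, noise_sd = noise_sd),
            class = "transient_window")
}

#' Through-origin linearization of one conversion law
#'
#' Regresses \eqn{y_i = g(X_i)} on \eqn{x_i = t_i} with no intercept, the
#' form \eqn{y = (1/\tau)\,t} that each single-resistance law takes. The
#' slope is \eqn{\sum x y / \sum x^2}; for the no-intercept model
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2/\sum y^2} and the adjusted value is
#' \eqn{1 - (1-R^2)\,n/(n-1)} (one parameter, no intercept). The standard
#' error is the residual standard error \eqn{\sqrt{RSS/(n-1)}}, on the scale
#' of the g-residuals.
#'
#' @param conv a [conversion_series()].
#' @param regime one of [scm_regimes()].
#' @param window optional `transient_window` (from [extract_transient()]);
#'   default uses all points.
#' @return a `regime_linearization` list: `regime`, `slope_inv_tau` (1/s),
#'   `adjusted_R2`, `standard_error`, `n_points`.
#' @export
linearize_fit <- function(conv, regime, window = NULL) {
  stopifnot(inherits(conv, "conversion_series"))
  regime <- match_regime(regime)
  idx <- if (is.null(window)) seq_along(conv$X) else window$idx
  x <- conv$times_s[idx]
  y <- g_regime(conv$X[idx], regime)
  n <- length(x)
  if (n < 3L) stop_input("need at least 3 points to linearize")
  if (all(y == 0)) stop_input("degenerate fit: all conversions are zero")
  sxx <- sum(x^2)
  if (sxx == 0) stop_input("degenerate fit: all times are zero")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  syy <- sum(y^2)
  r2 <- 1 - rss / syy
  adj <- 1 - (1 - r2) * n / (n - 1)
  structure(list(regime = regime, slope_inv_tau = slope,
                 adjusted_R2 = adj, r2 = r2,
                 standard_error = sqrt(rss / (n - 1)), n_points = n),
            class = "regime_linearization")
}

#' Select the rate-limiting regime
#'
#' The regime whose through-origin linearization has the highest adjusted
#' R\eqn{^2} is taken as the rate-limiting step. If the top two adjusted
#' R\eqn{^2} values differ by less than `tie_tolerance`, the selection is
#' flagged ambiguous (the winner is still reported, in the enumeration order
#' of [scm_regimes()]).
#'
#' @param linearizations named list of three `regime_linearization` objects,
#'   one per regime, fitted on the same window.
#' @param tie_tolerance adjusted-R\eqn{^2} gap below which a tie is flagged
#'   (default 0.005).
#' @return a `step_determination` list: `linearizations`, `selected`,
#'   `tie_flag`, `table` (one row per regime).
#' @export
select_regime <- function(linearizations, tie_tolerance = 0.005) {
  if (!all(scm_regimes() %in% names(linearizations)))
    stop_input("'linearizations' must be named with all three regimes")
  linearizations <- linearizations[scm_regimes()]
  adj <- vapply(linearizations, function(l) l$adjusted_R2, numeric(1))
  best <- which.max(adj)  # first maximum: deterministic enumeration order
  sorted <- sort(adj, decreasing = TRUE)
  tie_flag <- length(sorted) > 1L && (sorted[1] - sorted[2]) < tie_tolerance
  tab <- data.frame(
    regime = scm_regimes(),
    slope_inv_tau = vapply(linearizations, `[[`, numeric(1), "slope_inv_tau"),
    adjusted_R2 = adj,
    standard_error = vapply(linearizations, `[[`, numeric(1), "standard_error"),
    n_points = vapply(linearizations, `[[`, integer(1), "n_points"),
    row.names = NULL
  )
  structure(list(linearizations = linearizations,
                 selected = scm_regimes()[best],
                 tie_flag = tie_flag, tie_tolerance = tie_tolerance,
                 table = tab),
            class = "step_determination")
}

#' Full rate-limiting-step determination for one series
#'
#' Extracts the transient window, linearizes under all three candidate
#' regimes, and selects the rate-limiting step.
#'
#' @inheritParams extract_transient
#' @inheritParams select_regime
#' @return a `step_determination` (see [select_regime()]) with the `window`
#'   attached.
#' @examples
#' spec <- particle_spec_cu()
#' pars <- scm_parameters(D_e = 2.39e-11, C_s = 5.65e-8, N0 = 1.17e12)
#' ser <- forward_concentration("porous_shell", spec, pars,
#'                              hours_to_seconds(c(1, 2, 4, 8, 16, 24, 36, 48)),
#'                              volume_m3 = 1e-3)
#' determine_step(conversion_from_concentration(ser))$selected
#' @export
determine_step <- function(conv, plateau_fraction = 0.95,
                           enforce_monotone = TRUE, tie_tolerance = 0.005) {
  window <- extract_transient(conv, plateau_fraction, enforce_monotone)
  fits <- lapply(scm_regimes(), function(rg) linearize_fit(conv, rg, window))
  names(fits) <- scm_regimes()
  out <- select_regime(fits, tie_tolerance)
  out$window <- window
  out
}

#' @export
print.step_determination <- function(x, ...) {
  cat("Rate-limiting-step determination (through-origin linearization)\n")
  print(x$table, digits = 4)
  cat(sprintf("selected: %s%s\n", x$selected,
              if (x$tie_flag) "  [ambiguous: top two within tie tolerance]" else ""))
  invisible(x)
}
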