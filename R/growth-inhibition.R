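# Bacterial growth curves and the growth-inhibition indicator.
#
# The biocidal effect of a copper-modified membrane is scored by how much it
# slows exponential-phase growth of E. coli relative to the control:
#   I(%) = (mu_C - mu_B) / mu_C * 100,
# with mu the slope of ln(CFU) against time over the exponential window.
# I is invariant to the logarithm base, so natural log is used.

#' CFU growth curve
#'
#' @param times_h sampling times in hours, strictly increasing.
#' @param cfu_per_ml viable counts, CFU/mL. Zeros are replaced by
#'   `detection_floor / 2` (log transforms require positivity) and flagged.
#' @param label curve label (e.g. `"control"` or a membrane id).
#' @param detection_floor plating detection limit in CFU/mL used to floor
#'   zero counts (default 20, i.e. one colony from 50 uL of undiluted
#'   sample).
#' @return an object of class `growth_curve` with a `floored` flag.
#' @export
growth_curve <- function(times_h, cfu_per_ml, label = "curve",
                         detection_floor = 20) {
  if (length(times_h) != length(cfu_per_ml)) stop_input("length mismatch")
  if (any(!is.finite(times_h)) || any(diff(times_h) <= 0))
    stop_input("times must be finite and strictly increasing")
  if (any(!is.finite(cfu_per_ml)) || any(cfu_per_ml < 0))
    stop_input("CFU counts must be finite and >= 0")
  floored <- any(cfu_per_ml == 0)
  cfu_per_ml[cfu_per_ml == 0] <- detection_floor / 2
  structure(list(times_h = as.numeric(times_h),
                 cfu_per_ml = as.numeric(cfu_per_ml),
                 label = label, floored = floored),
            class = "growth_curve")
}

#' Exponential-phase growth rate
#'
#' Estimates \eqn{\mu} as the least-squares slope of \eqn{\ln(\mathrm{CFU})}
#' against time over the exponential window. If no window is given, the
#' window is chosen automatically: among all contiguous windows of at least
#' `min_points` points whose log-linear fit has \eqn{R^2 \ge} `min_r2`, take
#' the one with the largest slope; slope ties (within 1e-9 relative) go to
#' the longest window. If no window passes the linearity rule the max-slope
#' 3-point window is used with a warning.
#'
#' @param curve a [growth_curve()] with at least 4 points.
#' @param window optional integer index range to fit on.
#' @param min_r2 log-linearity requirement for automatic windowing.
#' @param min_points minimum window length.
#' @return list: `mu` (1/h), `se` (1/h), `window` (indices), `r2`,
#'   `fallback` flag.
#' @export
growth_rate <- function(curve, window = NULL, min_r2 = 0.98, min_points = 3L) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$times_h
  y <- log(curve$cfu_per_ml)
  n <- length(t)
  if (n < 4L) stop_input("need at least 4 points")

  slope_fit <- function(idx) {
    xt <- t[idx]; yt <- y[idx]
    m <- length(idx)
    sxx <- sum((xt - mean(xt))^2)
    slope <- sum((xt - mean(xt)) * (yt - mean(yt))) / sxx
    yhat <- mean(yt) + slope * (xt - mean(xt))
    rss <- sum((yt - yhat)^2)
    tss <- sum((yt - mean(yt))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1  # flat data: perfect flat fit
    se <- if (m > 2) sqrt(rss / (m - 2) / sxx) else NA_real_
    list(slope = slope, se = se, r2 = r2)
  }

  if (!is.null(window)) {
    f <- slope_fit(window)
    return(list(mu = f$slope, se = f$se, window = window, r2 = f$r2,
                fallback = FALSE))
  }

  cand <- list()
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      idx <- i:j
      f <- slope_fit(idx)
      cand[[length(cand) + 1L]] <- list(idx = idx, f = f)
    }
  }
  ok <- Filter(function(cc) cc$f$r2 >= min_r2, cand)
  fallback <- length(ok) == 0L
  if (fallback) {
    warning("no window meets the log-linearity rule; using max-slope 3-point window",
            call. = FALSE)
    ok <- Filter(function(cc) length(cc$idx) == 3L, cand)
  }
  slopes <- vapply(ok, function(cc) cc$f$slope, numeric(1))
  smax <- max(slopes)
  near <- abs(slopes - smax) <= 1e-9 * max(abs(smax), 1e-12)
  lens <- vapply(ok, function(cc) length(cc$idx), integer(1))
  pick <- which(near)[which.max(lens[near])]
  f <- ok[[pick]]$f
  list(mu = f$slope, se = f$se, window = ok[[pick]]$idx, r2 = f$r2,
       fallback = fallback)
}

#' Growth-inhibition indicator
#'
#' \deqn{I(\%) = \frac{\mu_C - \mu_B}{\mu_C} \times 100,}
#' the percent reduction of the treated exponential-phase growth rate
#' \eqn{\mu_B} relative to the control \eqn{\mu_C}. The standard error is
#' propagated by the delta method from the two slope standard errors.
#'
#' @param mu_C control growth rate, 1/h (> 0).
#' @param mu_B treated growth rate, 1/h.
#' @param se_C,se_B standard errors of the two rates (default 0).
#' @return list: `mu_C`, `mu_B`, `I_percent`, `se_I`.
#' @examples
#' inhibition_rate(0.50, 0.22)$I_percent  # 56
#' @export
inhibition_rate <- function(mu_C, mu_B, se_C = 0, se_B = 0) {
  check_number(mu_C, "mu_C")
  check_number(mu_B, "mu_B")
  if (mu_C <= 0)
    stop_input("inhibition undefined: control growth rate must be > 0")
  I <- (mu_C - mu_B) / mu_C * 100
  # delta method: dI/dmu_C = 100 mu_B / mu_C^2, dI/dmu_B = -100 / mu_C
  se_I <- 100 * sqrt((mu_B * se_C / mu_C^2)^2 + (se_B / mu_C)^2)
  list(mu_C = mu_C, mu_B = mu_B, I_percent = I, se_I = se_I)
}

#' Inhibition report for treated curves against a control
#'
#' Runs [growth_rate()] on the control and each treated curve and tabulates
#' the inhibition indicator with its propagated standard error, one row per
#' treatment (the layout of a membrane-inhibition summary table).
#'
#' @param control a [growth_curve()] for the control culture.
#' @param treated a list of [growth_curve()]s for the treatments.
#' @param ... passed to [growth_rate()].
#' @return data.frame: `label`, `mu_C`, `mu_B`, `I_percent`, `se_I`.
#' @export
inhibition_report <- function(control, treated, ...) {
  stopifnot(inherits(control, "growth_curve"))
  if (inherits(treated, "growth_curve")) treated <- list(treated)
  gc_C <- growth_rate(control, ...)
  rows <- lapply(treated, function(cv) {
    stopifnot(inherits(cv, "growth_curve"))
    gc_B <- growth_rate(cv, ...)
    r <- inhibition_rate(gc_C$mu, gc_B$mu, gc_C$se, gc_B$se)
    data.frame(label = cv$label, mu_C = r$mu_C, mu_B = r$mu_B,
               I_percent = r$I_percent, se_I = r$se_I)
  })
  do.call(rbind, rows)
}
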