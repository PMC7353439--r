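# Delimited-text I/O and end-to-end analysis reports. Files use laboratory
# units (hours, mg/L, CFU/mL); everything is converted to SI at this
# boundary.

read_numeric_csv <- function(path, required) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_input("no data rows in %s", path)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_input("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop_input("%s: non-numeric or missing '%s' at data row(s) %s",
                 path, col, paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Read a dissolved-ion time series from CSV
#'
#' Expects columns `time` and `conc_mg_l` (concentration in mg/L); `time` is
#' in hours unless `time_unit = "s"`. Malformed rows raise a line-numbered
#' parse error.
#'
#' @param path CSV path.
#' @param volume_l solution volume in litres.
#' @param initial_copper_g initial copper mass in grams.
#' @param time_unit `"h"` (default) or `"s"`.
#' @return a [dissolution_series()].
#' @export
read_dissolution_csv <- function(path, volume_l = 1, initial_copper_g = 2.5,
                                 time_unit = c("h", "s")) {
  time_unit <- match.arg(time_unit)
  df <- read_numeric_csv(path, c("time", "conc_mg_l"))
  t_s <- if (time_unit == "h") hours_to_seconds(df$time) else df$time
  # measured data may exceed the nominal mass bound through measurement
  # error; the conversion step records the inconsistency
  dissolution_series(t_s, mg_per_l_to_kg_per_m3(df$conc_mg_l),
                     litres_to_m3(volume_l), grams_to_kg(initial_copper_g),
                     check_mass = FALSE)
}

#' Write a dissolution series to CSV (hours, mg/L)
#'
#' @param series a [dissolution_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(series, path) {
  stopifnot(inherits(series, "dissolution_series"))
  utils::write.csv(
    data.frame(time = seconds_to_hours(series$times_s),
               conc_mg_l = kg_per_m3_to_mg_per_l(series$conc_kg_m3)),
    path, row.names = FALSE)
  invisible(path)
}

#' Convert a concentration CSV to a conversion CSV
#'
#' File-level wrapper over [conversion_from_concentration()]: reads time +
#' concentration, writes time (h) + conversion X.
#'
#' @inheritParams read_dissolution_csv
#' @param out_path output CSV path.
#' @return the [conversion_series()], invisibly.
#' @export
convert_file <- function(path, out_path, volume_l = 1, initial_copper_g = 2.5,
                         time_unit = "h") {
  ser <- read_dissolution_csv(path, volume_l, initial_copper_g, time_unit)
  conv <- conversion_from_concentration(ser)
  utils::write.csv(data.frame(time = seconds_to_hours(conv$times_s),
                              X = conv$X),
                   out_path, row.names = FALSE)
  invisible(conv)
}

#' Read a CFU growth curve from CSV
#'
#' Expects columns `time_h`, `cfu_per_ml` and optionally `label`.
#'
#' @param path CSV path.
#' @param label curve label; defaults to the file's `label` column (first
#'   value) or the file name.
#' @return a [growth_curve()].
#' @export
read_growth_csv <- function(path, label = NULL) {
  df <- read_numeric_csv(path, c("time_h", "cfu_per_ml"))
  if (is.null(label))
    label <- if ("label" %in% names(df)) as.character(df$label[1])
             else basename(path)
  growth_curve(df$time_h, df$cfu_per_ml, label)
}

#' Write a growth curve to CSV
#'
#' @param curve a [growth_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  utils::write.csv(data.frame(time_h = curve$times_h,
                              cfu_per_ml = curve$cfu_per_ml,
                              label = curve$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' End-to-end dissolution analysis for one sample
#'
#' The full workflow for one ion-release curve: conversion, transient
#' window, three-regime linearization, regime selection, then the nonlinear
#' fit under the selected regime — the shrinking-core fit for particle
#' species, or the Nernst-Brunner fit when `model = "nernst_brunner"`
#' (membrane-complexed copper with no particle count).
#'
#' @param series a [dissolution_series()].
#' @param spec a [particle_spec()].
#' @param model `"scm"` or `"nernst_brunner"`.
#' @param C_s driving concentration for the SCM fit (kg/m\eqn{^3}).
#' @param plateau_fraction,tie_tolerance step-determination options.
#' @param ci_method `"covariance"` or `"bootstrap"`.
#' @param sample_name label used in reports.
#' @return an `scm_analysis` list: `sample`, `step` (a `step_determination`),
#'   `fit` (an `scm_fit` or `nb_fit`), `conversion`.
#' @export
analyze_dissolution <- function(series, spec, model = c("scm", "nernst_brunner"),
                                C_s = 1, plateau_fraction = 0.95,
                                tie_tolerance = 0.005,
                                ci_method = "covariance",
                                sample_name = spec$species_label) {
  model <- match.arg(model)
  conv <- conversion_from_concentration(series, spec)
  step <- determine_step(conv, plateau_fraction = plateau_fraction,
                         tie_tolerance = tie_tolerance)
  fit <- if (model == "scm") {
    fit_scm(series, step$selected, spec, C_s = C_s, ci_method = ci_method)
  } else {
    fit_nernst_brunner(series, ci_method = ci_method)
  }
  structure(list(sample = sample_name, model = model, step = step,
                 fit = fit, conversion = conv),
            class = "scm_analysis")
}

#' Tabulate linearization results across samples
#'
#' One row per sample and regime (slope, adjusted R\eqn{^2}, standard error,
#' n), the layout of a rate-limiting-step summary table.
#'
#' @param analyses list of `scm_analysis` objects from
#'   [analyze_dissolution()].
#' @return data.frame.
#' @export
step_table <- function(analyses) {
  if (inherits(analyses, "scm_analysis")) analyses <- list(analyses)
  rows <- lapply(analyses, function(a) {
    tab <- a$step$table
    tab$sample <- a$sample
    tab$selected <- tab$regime == a$step$selected
    tab[, c("sample", "regime", "slope_inv_tau", "adjusted_R2",
            "standard_error", "n_points", "selected")]
  })
  do.call(rbind, rows)
}

#' Tabulate fitted parameters across samples
#'
#' One row per sample: fitted kinetic parameters with confidence half-widths
#' and goodness of fit, the layout of a dissolution-fit summary table.
#' Concentrations are reported in mg/L.
#'
#' @inheritParams step_table
#' @return data.frame.
#' @export
fit_table <- function(analyses) {
  if (inherits(analyses, "scm_analysis")) analyses <- list(analyses)
  rows <- lapply(analyses, function(a) {
    f <- a$fit
    if (inherits(f, "scm_fit")) {
      data.frame(sample = a$sample, model = "scm", regime = f$regime,
                 D_e = f$D_e, ci_D_e = unname(f$ci$half_width[[f$constant_name]]),
                 N0 = f$N0, ci_N0 = unname(f$ci$half_width[["N0"]]),
                 C_sat_mg_l = NA_real_, ci_C_sat = NA_real_,
                 r2_fit = f$r2_fit, mse = f$mse)
    } else {
      data.frame(sample = a$sample, model = "nernst_brunner", regime = "porous_shell",
                 D_e = f$D_e, ci_D_e = NA_real_,
                 N0 = NA_real_, ci_N0 = NA_real_,
                 C_sat_mg_l = kg_per_m3_to_mg_per_l(f$C_sat),
                 ci_C_sat = kg_per_m3_to_mg_per_l(unname(f$ci$half_width[["C_sat"]])),
                 r2_fit = f$r2_fit, mse = f$mse)
    }
  })
  do.call(rbind, rows)
}

#' Write an analysis report as JSON
#'
#' Machine-readable analogue of the step-determination and fit tables:
#' per-sample transient window, three linearizations, selected regime, and
#' fitted parameters with confidence half-widths. All options and units are
#' embedded for provenance.
#'
#' @param analyses list of `scm_analysis` objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(analyses, path) {
  if (inherits(analyses, "scm_analysis")) analyses <- list(analyses)
  payload <- lapply(analyses, function(a) {
    f <- a$fit
    fit_part <- if (inherits(f, "scm_fit")) {
      list(model = "scm", regime = f$regime,
           parameters = as.list(f$par),
           C_s_fixed = f$C_s,
           ci_half_width = as.list(f$ci$half_width),
           ci_method = f$ci$method, alpha = f$ci$alpha,
           mse = f$mse, r2_fit = f$r2_fit, converged = f$converged)
    } else {
      list(model = "nernst_brunner",
           parameters = list(k = f$k, C_sat = f$C_sat, D_e = f$D_e),
           ci_half_width = as.list(f$ci$half_width),
           ci_method = f$ci$method, alpha = f$ci$alpha,
           mse = f$mse, r2_fit = f$r2_fit, converged = f$converged)
    }
    list(sample = a$sample,
         conversion_inconsistent = a$conversion$inconsistent,
         transient_window = list(
           idx = a$step$window$idx,
           excluded = a$step$window$excluded,
           plateau_fraction = a$step$window$plateau_fraction),
         linearization = a$step$table,
         selected_regime = a$step$selected,
         tie_flag = a$step$tie_flag,
         fit = fit_part)
  })
  names(payload) <- vapply(analyses, `[[`, character(1), "sample")
  jsonlite::write_json(
    list(units = list(time = "s", concentration = "kg/m3",
                      D_e = "m2/s", k = "1/s"),
         samples = payload),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
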