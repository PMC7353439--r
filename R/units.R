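# Unit conversions between the package's internal SI units (s, m, kg, kg/m3)
# and the units the laboratory I/O uses (h, mg/L, L, g). All model code works
# in SI; conversion happens once at the boundary.

#' Unit conversion helpers
#'
#' Internally every computation uses SI units: seconds, metres, kilograms and
#' kg/m\eqn{^3}. Data files and reports use the laboratory units of the ion
#' release protocol: hours, mg/L and litres. Note that 1 mg/L = 1 g/m\eqn{^3}
#' = 1e-3 kg/m\eqn{^3}.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
hours_to_seconds <- function(x) x * 3600

#' @rdname units
#' @export
seconds_to_hours <- function(x) x / 3600

#' @rdname units
#' @export
mg_per_l_to_kg_per_m3 <- function(x) x * 1e-3

#' @rdname units
#' @export
kg_per_m3_to_mg_per_l <- function(x) x * 1e3

#' @rdname units
#' @export
litres_to_m3 <- function(x) x * 1e-3

#' @rdname units
#' @export
grams_to_kg <- function(x) x * 1e-3

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps generator determinism local: calling a seeded generator does not
# disturb an enclosing simulation loop.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_input("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_input("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
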