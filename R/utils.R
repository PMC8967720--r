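#' Round a monetary amount half-up to the penny
#'
#' Presentation-level rounding. Internal arithmetic is kept at full double
#' precision; amounts are only snapped to the penny when reported, using
#' half-up rounding (0.005 -> 0.01) rather than R's banker's rounding.
#'
#' @param x numeric vector of amounts in pounds.
#' @return `x` rounded half-up to 2 decimal places.
#' @export
round_money <- function(x) {
  # 1e-9 guards against 0.005 stored as 0.004999...
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

#' Convert a duration in working days to hours
#'
#' @param days numeric, duration in working days.
#' @param hours_per_day working hours per day; default 7, consistent with a
#'   1.5-day training input costing 10.5 h.
#' @return hours.
#' @export
days_to_hours <- function(days, hours_per_day = 7) {
  stopifnot(is.numeric(days), days >= 0, hours_per_day > 0)
  days * hours_per_day
}

# internal: scalar validation helpers
assert_scalar_num <- function(x, name, lower = -Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  }
  if (!is.na(x) && x < lower) {
    stop(sprintf("'%s' must be >= %s (got %s)", name, lower, x), call. = FALSE)
  }
  invisible(x)
}

# internal: derive a vector of independent sub-seeds from one master seed,
# each below 2^31 so they are valid R integer seeds
spawn_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
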