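#' Supported preference-based instruments
#'
#' Dimension structure of the health-state descriptive systems handled by the
#' valuation module. `EQ5D5L_crosswalk` is the EQ-5D-5L descriptive system
#' valued on the EQ-5D-3L tariff via the published crosswalk (its value set
#' has floor -0.594); `EQ5D5L` is the 5L system on its own tariff (floor
#' -0.285); `EQ5D3L` the 3L system; `SF6D` the six-dimension short-form
#' index (floor 0.203). The tariffs themselves are consumed as lookup-table
#' inputs, never re-derived.
#'
#' @param instrument instrument code.
#' @return integer vector: number of levels per dimension.
#' @export
instrument_levels <- function(instrument) {
  switch(instrument,
    EQ5D5L            = rep(5L, 5),
    EQ5D5L_crosswalk  = rep(5L, 5),
    EQ5D3L            = rep(3L, 5),
    SF6D              = c(6L, 4L, 5L, 6L, 5L, 5L),
    stop("unsupported instrument: ", instrument, call. = FALSE)
  )
}

# documented floors of the instruments' value sets (worst-profile utility)
instrument_floor <- function(instrument) {
  switch(instrument,
    EQ5D5L           = -0.285,
    EQ5D5L_crosswalk = -0.594,
    EQ5D3L           = -0.594,
    SF6D             = 0.203,
    stop("unsupported instrument: ", instrument, call. = FALSE)
  )
}

#' Health-state profile
#'
#' @param instrument instrument code (see [instrument_levels()]).
#' @param levels integer vector of dimension levels (1 = no problems).
#' @return `health_profile` object.
#' @export
health_profile <- function(instrument, levels) {
  maxlev <- instrument_levels(instrument)
  levels <- as.integer(levels)
  if (length(levels) != length(maxlev)) {
    stop(sprintf("%s profiles have %d dimensions, got %d", instrument,
                 length(maxlev), length(levels)), call. = FALSE)
  }
  if (any(levels < 1L) || any(levels > maxlev)) {
    stop("profile levels out of range for ", instrument, call. = FALSE)
  }
  structure(list(instrument = instrument, levels = levels),
            class = "health_profile")
}

#' @rdname health_profile
#' @param x a `health_profile`.
#' @export
profile_key <- function(x) paste(x$levels, collapse = "-")

#' Value-set lookup table
#'
#' Maps every health-state profile of an instrument to a preference-based
#' utility. The full-health profile (all 1s) must map to 1; all utilities
#' must lie in `[floor, 1]`.
#'
#' @param instrument instrument code.
#' @param profiles character vector of hyphenated profile keys, e.g.
#'   `"1-2-1-1-3"`.
#' @param utilities numeric vector of the same length.
#' @param floor minimum utility of the tariff.
#' @return `value_set` object.
#' @export
value_set <- function(instrument, profiles, utilities, floor) {
  stopifnot(length(profiles) == length(utilities))
  instrument_levels(instrument) # validates code
  if (any(utilities > 1 + 1e-9) || any(utilities < floor - 1e-9)) {
    stop("value set utilities must lie in [floor, 1]", call. = FALSE)
  }
  full <- paste(rep(1L, length(instrument_levels(instrument))), collapse = "-")
  ifull <- match(full, profiles)
  if (is.na(ifull) || abs(utilities[ifull] - 1) > 1e-9) {
    stop("full-health profile must be present and map to 1.0", call. = FALSE)
  }
  map <- utilities
  names(map) <- profiles
  structure(list(instrument = instrument, map = map, floor = floor,
                 ceiling = 1.0),
            class = "value_set")
}

#' Read a value set from CSV
#'
#' Expected columns: `profile` (hyphenated levels) and `utility`; the
#' instrument and floor are taken from `instrument`/`floor` columns if
#' present, otherwise from the arguments.
#'
#' @param path CSV path.
#' @param instrument,floor used when the file has no such columns.
#' @return a [value_set()].
#' @export
read_value_set <- function(path, instrument = NULL, floor = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(profile = "character"))
  if (is.null(instrument)) instrument <- df$instrument[1]
  if (is.null(floor)) floor <- if ("floor" %in% names(df)) df$floor[1] else min(df$utility)
  value_set(instrument, df$profile, df$utility, floor)
}

#' Look up the utility of a health-state profile
#'
#' @param profile a [health_profile()] or a character profile key.
#' @param vs a [value_set()].
#' @return tabulated utility (deterministic).
#' @export
lookup_utility <- function(profile, vs) {
  stopifnot(inherits(vs, "value_set"))
  if (inherits(profile, "health_profile")) {
    if (profile$instrument != vs$instrument) {
      stop(sprintf("instrument mismatch: profile is %s, value set is %s",
                   profile$instrument, vs$instrument), call. = FALSE)
    }
    key <- profile_key(profile)
  } else {
    key <- as.character(profile)
  }
  u <- unname(vs$map[key])
  if (anyNA(u)) {
    stop("profile(s) absent from value set: ",
         paste(key[is.na(u)], collapse = ", "), call. = FALSE)
  }
  u
}

#' Discounted QALYs over 24 months by area under the utility curve
#'
#' Trapezoidal areas over months 0-6, 6-12 and 12-24, weighted by interval
#' length in years. The 12-24-month area falls in the second year after
#' randomisation and is discounted as one block by `1/(1+r)`; the first year
#' is undiscounted.
#'
#' Missing utilities are an error by design: imputation is the missing-data
#' module's responsibility and must happen before QALY calculation.
#'
#' @param u0,u6,u12,u24 utilities at months 0, 6, 12 and 24 (vectors are
#'   recycled elementwise).
#' @param discount_rate annual rate, default 0.035.
#' @return QALYs (same length as the inputs).
#' @examples
#' qaly_auc(1, 1, 1, 1, discount_rate = 0)     # 2
#' qaly_auc(1, 1, 1, 1)                        # 1 + 1/1.035
#' @export
qaly_auc <- function(u0, u6, u12, u24, discount_rate = 0.035) {
  if (anyNA(c(u0, u6, u12, u24))) {
    stop("missing utilities: impute before computing QALYs", call. = FALSE)
  }
  if (any(c(u0, u6, u12, u24) > 1 + 1e-9)) {
    stop("utilities cannot exceed 1", call. = FALSE)
  }
  assert_scalar_num(discount_rate, "discount_rate", lower = 0)
  year1 <- (u0 + u6) / 2 * 0.5 + (u6 + u12) / 2 * 0.5
  year2 <- (u12 + u24) / 2 * 1
  year1 + year2 / (1 + discount_rate)
}
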