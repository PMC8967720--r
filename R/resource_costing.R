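#' Unit-cost table for NHS/PSS resource items
#'
#' @param items character vector of resource item names.
#' @param unit_costs non-negative unit costs (GBP).
#' @param price_year price year the costs are expressed in (metadata).
#' @param source provenance note per item (metadata), recycled.
#' @return `unit_cost_table` object.
#' @export
unit_cost_table <- function(items, unit_costs, price_year = "2018-19",
                            source = NA_character_) {
  stopifnot(length(items) == length(unit_costs), !anyNA(unit_costs),
            all(unit_costs >= 0), !anyDuplicated(items))
  costs <- as.numeric(unit_costs)
  names(costs) <- items
  structure(list(costs = costs, price_year = price_year,
                 source = rep_len(source, length(items))),
            class = "unit_cost_table")
}

#' Read a unit-cost table from CSV
#'
#' Expected columns: `item`, `unit_cost`; optional `price_year`, `source`.
#' @param path CSV path.
#' @return a [unit_cost_table()].
#' @export
read_unit_costs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit_cost_table(df$item, df$unit_cost,
                  price_year = if ("price_year" %in% names(df)) df$price_year[1] else NA,
                  source = if ("source" %in% names(df)) df$source else NA_character_)
}

#' Cost of one 6-month recall period
#'
#' Dot product of resource-use counts with unit costs. Every counted item
#' must be priced: an unpriced item is an error, never a silent zero.
#'
#' @param counts named numeric vector (or 1-row data frame) of non-negative
#'   counts per resource item.
#' @param prices a [unit_cost_table()].
#' @return period cost (GBP).
#' @export
period_cost <- function(counts, prices) {
  stopifnot(inherits(prices, "unit_cost_table"))
  if (is.data.frame(counts)) counts <- unlist(counts[1, , drop = TRUE])
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by resource item", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  unpriced <- setdiff(names(counts), names(prices$costs))
  if (length(unpriced)) {
    stop("no unit cost for item(s): ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) return(NA_real_)
  sum(counts * prices$costs[names(counts)])
}

#' Impute the unmeasured 12-18-month period cost
#'
#' Resource use is recalled over 6-month windows at the 6, 12 and 24-month
#' assessments, leaving months 12-18 unobserved; its cost is taken as the
#' arithmetic mean of the two neighbouring observed periods. Run after
#' multiple imputation so both neighbours are resolved.
#'
#' @param cost_6_12,cost_18_24 period costs (GBP), no missing values.
#' @return imputed 12-18-month cost.
#' @export
impute_gap_period <- function(cost_6_12, cost_18_24) {
  if (anyNA(cost_6_12) || anyNA(cost_18_24)) {
    stop("neighbouring period costs must be complete (run multiple imputation first)",
         call. = FALSE)
  }
  (cost_6_12 + cost_18_24) / 2
}

#' Discounted 24-month total cost
#'
#' Year-1 period costs (0-6, 6-12 months) are undiscounted; year-2 costs
#' (12-18, 18-24 months) are discounted by `1/(1+r)`. The intervention
#' delivery cost is attributed entirely to year 1 and not discounted.
#'
#' @param cost_0_6,cost_6_12,cost_12_18,cost_18_24 period costs (GBP,
#'   vectors recycled elementwise, all non-negative).
#' @param intervention_cost per-participant delivery cost (default 0).
#' @param discount_rate annual rate, default 0.035.
#' @return total discounted 24-month cost.
#' @export
total_24m_cost <- function(cost_0_6, cost_6_12, cost_12_18, cost_18_24,
                           intervention_cost = 0, discount_rate = 0.035) {
  costs <- c(cost_0_6, cost_6_12, cost_12_18, cost_18_24, intervention_cost)
  if (anyNA(costs)) stop("period costs must be complete", call. = FALSE)
  if (any(costs < 0)) stop("period costs must be non-negative", call. = FALSE)
  assert_scalar_num(discount_rate, "discount_rate", lower = 0)
  (cost_0_6 + cost_6_12) +
    (cost_12_18 + cost_18_24) / (1 + discount_rate) +
    intervention_cost
}
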