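#' Cost component of a group programme
#'
#' One resource line of the intervention micro-costing: a quantity of a
#' resource (hours, items) with a unit cost and a costing basis that says how
#' the quantity scales to a 12-month programme delivered to one group.
#'
#' @param label character, resource name.
#' @param basis one of `"per_session"` (quantity consumed at every session),
#'   `"per_participant"` (quantity per group member), `"per_group"` (fixed
#'   quantity per programme) or `"per_programme_share"` (fixed quantity whose
#'   cost is shared across `share_divisor` programmes, e.g. trainer time for
#'   four trainees each delivering four programmes).
#' @param quantity non-negative quantity per basis unit (hours or items;
#'   convert minutes to hours, days via [days_to_hours()]).
#' @param unit_cost money per unit of quantity, GBP.
#' @param share_divisor positive integer, number of programmes sharing the
#'   cost (only used for `per_programme_share`); default 1.
#' @return an object of class `cost_component`.
#' @seealso [component_cost()], [programme_cost()], [annuitize()]
#' @export
cost_component <- function(label, basis, quantity, unit_cost, share_divisor = 1L) {
  basis <- match.arg(basis, c("per_session", "per_participant", "per_group",
                              "per_programme_share"))
  assert_scalar_num(quantity, "quantity", lower = 0)
  assert_scalar_num(unit_cost, "unit_cost", lower = 0)
  assert_scalar_num(share_divisor, "share_divisor", lower = 1)
  structure(
    list(label = as.character(label), basis = basis, quantity = quantity,
         unit_cost = unit_cost, share_divisor = as.integer(share_divisor)),
    class = "cost_component"
  )
}

#' Per-group cost of one component
#'
#' Scales a [cost_component()] to a whole programme:
#' \itemize{
#'   \item `per_session`: quantity x n_sessions x unit_cost
#'   \item `per_participant`: quantity x group_size x unit_cost
#'   \item `per_group`: quantity x unit_cost
#'   \item `per_programme_share`: quantity x unit_cost / share_divisor
#' }
#' Arithmetic is exact at double precision; round with [round_money()] only
#' when presenting.
#'
#' @param component a [cost_component()].
#' @param n_sessions non-negative integer, sessions per programme.
#' @param group_size positive real, average participants per group.
#' @return cost per group (GBP, unrounded).
#' @examples
#' delivery <- cost_component("delivery", "per_session", 1.5, 29.43)
#' component_cost(delivery, n_sessions = 64, group_size = 15.2) # 2825.28
#' @export
component_cost <- function(component, n_sessions, group_size) {
  stopifnot(inherits(component, "cost_component"))
  assert_scalar_num(n_sessions, "n_sessions", lower = 0)
  assert_scalar_num(group_size, "group_size")
  if (group_size <= 0) stop("'group_size' must be > 0", call. = FALSE)
  switch(component$basis,
    per_session         = component$quantity * n_sessions * component$unit_cost,
    per_participant     = component$quantity * group_size * component$unit_cost,
    per_group           = component$quantity * component$unit_cost,
    per_programme_share = component$quantity * component$unit_cost / component$share_divisor
  )
}

#' Equivalent annual cost of a capital item
#'
#' Spreads a capital outlay over its useful life with a discount-rate-based
#' annuity factor. With payments in arrears the factor is
#' \eqn{(1 - (1+r)^{-n})/r}; in advance it is that multiplied by \eqn{(1+r)}.
#' At \eqn{r = 0} both degenerate to straight-line `capital / lifetime_years`.
#'
#' @param capital money (GBP).
#' @param lifetime_years positive integer, useful life in years.
#' @param discount_rate annual discount rate in `[0, 1)`; default 0.035.
#' @param timing `"in_advance"` (default; payments at period start) or
#'   `"in_arrears"`.
#' @return equivalent annual cost (GBP, unrounded).
#' @examples
#' annuitize(136.27, 5, 0.035)                        # 29.16 in advance
#' annuitize(136.27, 5, 0.035, timing = "in_arrears") # 30.18
#' @export
annuitize <- function(capital, lifetime_years, discount_rate = 0.035,
                      timing = c("in_advance", "in_arrears")) {
  timing <- match.arg(timing)
  assert_scalar_num(capital, "capital", lower = 0)
  assert_scalar_num(discount_rate, "discount_rate", lower = 0)
  assert_scalar_num(lifetime_years, "lifetime_years")
  if (lifetime_years < 1) stop("'lifetime_years' must be >= 1", call. = FALSE)
  n <- lifetime_years
  r <- discount_rate
  if (r == 0) return(capital / n)
  af <- (1 - (1 + r)^(-n)) / r
  if (timing == "in_advance") af <- af * (1 + r)
  capital / af
}

#' Aggregate a programme costing
#'
#' Applies [component_cost()] to every component, sums the per-group column
#' and divides by the average group size for the per-participant column.
#'
#' @param components list of [cost_component()] objects (may be empty).
#' @param n_sessions sessions per programme.
#' @param group_size average participants per group.
#' @return a `programme_costing` object: a data frame of per-component costs
#'   (`label`, `basis`, `cost_per_group`, `cost_per_participant`) with
#'   attributes `total_per_group`, `total_per_participant`, `group_size`,
#'   `n_sessions`.
#' @export
programme_cost <- function(components, n_sessions, group_size) {
  stopifnot(is.list(components))
  per_group <- vapply(components, component_cost, numeric(1),
                      n_sessions = n_sessions, group_size = group_size)
  tab <- data.frame(
    label = vapply(components, function(cc) cc$label, character(1)),
    basis = vapply(components, function(cc) cc$basis, character(1)),
    cost_per_group = as.numeric(per_group),
    cost_per_participant = as.numeric(per_group) / group_size,
    stringsAsFactors = FALSE
  )
  structure(tab,
            total_per_group = sum(tab$cost_per_group),
            total_per_participant = sum(tab$cost_per_group) / group_size,
            group_size = group_size, n_sessions = n_sessions,
            class = c("programme_costing", "data.frame"))
}

#' @export
print.programme_costing <- function(x, ...) {
  cat("Programme costing (", attr(x, "n_sessions"), " sessions, group size ",
      attr(x, "group_size"), ")\n", sep = "")
  shown <- data.frame(label = x$label,
                      per_group = sprintf("%.2f", round_money(x$cost_per_group)),
                      per_participant = sprintf("%.2f", round_money(x$cost_per_participant)))
  print(shown, row.names = FALSE)
  cat(sprintf("Total: %.2f per group, %.2f per participant\n",
              round_money(attr(x, "total_per_group")),
              round_money(attr(x, "total_per_participant"))))
  invisible(x)
}

#' Read a costing specification file
#'
#' Reads one cost component per row/entry from CSV or YAML. Recognised
#' fields: `label`, `basis`, `quantity`, `unit_cost`, `share_divisor`
#' (optional, default 1) and, for capital items costed at their equivalent
#' annual cost, `capital`, `lifetime_years`, `annuity_rate`,
#' `annuity_timing` (in which case `unit_cost` is computed by [annuitize()]
#' and `quantity` defaults to 1).
#'
#' @param path file path (`.csv`, `.yaml` or `.yml`).
#' @return list of [cost_component()] objects.
#' @export
read_costing_spec <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
    if (!is.null(rows$components)) rows <- rows$components
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    rows <- split(df, seq_len(nrow(df)))
    rows <- lapply(rows, as.list)
  }
  lapply(rows, function(rw) {
    has_annuity <- !is.null(rw$capital) && !is.na(rw$capital) && rw$capital != ""
    if (has_annuity) {
      uc <- annuitize(as.numeric(rw$capital), as.numeric(rw$lifetime_years),
                      as.numeric(rw$annuity_rate),
                      timing = if (is.null(rw$annuity_timing) || rw$annuity_timing == "")
                        "in_advance" else rw$annuity_timing)
      qty <- if (is.null(rw$quantity) || is.na(rw$quantity)) 1 else as.numeric(rw$quantity)
    } else {
      uc <- as.numeric(rw$unit_cost)
      qty <- as.numeric(rw$quantity)
    }
    sd_ <- if (is.null(rw$share_divisor) || is.na(rw$share_divisor)) 1L else as.integer(rw$share_divisor)
    cost_component(rw$label, rw$basis, qty, uc, sd_)
  })
}
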