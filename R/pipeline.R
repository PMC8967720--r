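#' Build the participant-level analysis table
#'
#' Converts EQ-5D profile strings to utilities via the value set and
#' resource-use counts to period costs via the unit-cost table, preserving
#' missingness as `NA` (a period with any missing count has a missing
#' cost).
#'
#' @param trial a [generate_trial()] result, or a list with `participants`
#'   and `resource_use` in the same layout.
#' @param vs value set for the EQ-5D profiles; defaults to the trial's own.
#' @param prices a [unit_cost_table()]; defaults to [default_unit_costs()].
#' @return data frame: id, arm, age, sex, site, attendance, utilities
#'   `u0`/`u6`/`u12`/`u24`, and period costs `cost_base`, `cost_0_6`,
#'   `cost_6_12`, `cost_18_24`.
#' @export
prepare_analysis_data <- function(trial, vs = NULL, prices = default_unit_costs()) {
  pp <- trial$participants
  ru <- trial$resource_use
  if (is.null(vs)) vs <- trial$value_set
  if (is.null(vs)) vs <- generate_value_set("EQ5D5L_crosswalk")
  lk <- function(keys) {
    out <- rep(NA_real_, length(keys))
    ok <- !is.na(keys)
    if (any(ok)) out[ok] <- lookup_utility(keys[ok], vs)
    out
  }
  ru$costed <- ru$count * prices$costs[ru$item]
  cm <- tapply(ru$costed, list(factor(ru$id, levels = pp$id), ru$period), sum)
  data.frame(
    id = pp$id, arm = pp$arm, age = pp$age, sex = pp$sex, site = pp$site,
    attendance = pp$attendance,
    u0 = lk(pp$eq5d_0m), u6 = lk(pp$eq5d_6m), u12 = lk(pp$eq5d_12m),
    u24 = lk(pp$eq5d_24m),
    cost_base = cm[, "baseline"], cost_0_6 = cm[, "0-6"],
    cost_6_12 = cm[, "6-12"], cost_18_24 = cm[, "18-24"],
    stringsAsFactors = FALSE
  )
}

# internal: per-participant QALYs and discounted total costs for one
# completed dataset
complete_outcomes <- function(dat, intervention_cost, discount_rate) {
  gap <- impute_gap_period(dat$cost_6_12, dat$cost_18_24)
  dat$total_cost <- total_24m_cost(
    dat$cost_0_6, dat$cost_6_12, gap, dat$cost_18_24,
    intervention_cost = intervention_cost * (dat$arm == "intervention"),
    discount_rate = discount_rate)
  dat$qaly <- qaly_auc(dat$u0, dat$u6, dat$u12, dat$u24,
                       discount_rate = discount_rate)
  dat
}

#' Within-trial cost-utility analysis with multiple imputation
#'
#' The base-case analysis chain: multiple imputation of missing utilities
#' and period costs by [pmm_impute()]; per completed dataset the 12-18-month
#' gap cost is imputed deterministically, discounted 24-month totals and
#' QALYs computed, and covariate-adjusted arm contrasts estimated by
#' [adjusted_increment()]; results pooled by Rubin's rules; the pooled
#' increments classified by [classify_icer()]. Optionally bootstraps within
#' each imputation (pooling draws across imputations) to produce a CEAC.
#'
#' @param analysis output of [prepare_analysis_data()].
#' @param m imputations (default 50).
#' @param seed master seed.
#' @param intervention_cost per-participant delivery cost added to the
#'   intervention arm's totals (default 622 GBP).
#' @param discount_rate annual rate (default 0.035).
#' @param covariates adjustment covariates (default: age, sex, site,
#'   baseline utility, baseline cost).
#' @param granularity ICER reporting granularity.
#' @param B total bootstrap replicates across imputations (0 = skip).
#' @param iterations,k_donors passed to [pmm_impute()].
#' @param family GLM family for both outcomes.
#' @return `trial_cea` object: pooled QALY and cost increments
#'   (`pooled_qaly`, `pooled_cost` as [pool_estimates()] results),
#'   `classification`, and when `B > 0` the `draws` and `ceac`.
#' @export
run_trial_cea <- function(analysis, m = 50, seed = 1, intervention_cost = 622,
                          discount_rate = 0.035,
                          covariates = c("age", "sex", "site", "u0", "cost_base"),
                          granularity = 50, B = 0, iterations = 10,
                          k_donors = 5, family = "gaussian_identity") {
  dat <- analysis[setdiff(names(analysis), "id")]
  imps <- pmm_impute(dat, m = m, k_donors = k_donors, iterations = iterations,
                     seed = seed,
                     predictors = c("arm", "age", "sex", "site", "attendance"))
  est_q <- var_q <- est_c <- var_c <- numeric(m)
  all_draws <- vector("list", if (B > 0) m else 0)
  b_each <- if (B > 0) ceiling(B / m) else 0
  bseeds <- if (B > 0) spawn_seeds(seed + 1L, m) else integer(0)
  for (j in seq_len(m)) {
    cd <- complete_outcomes(imps[[j]], intervention_cost, discount_rate)
    aq <- adjusted_increment(cd, "qaly", covariates = covariates, family = family)
    ac <- adjusted_increment(cd, "total_cost", covariates = covariates,
                             family = family)
    est_q[j] <- aq$estimate; var_q[j] <- aq$variance
    est_c[j] <- ac$estimate; var_c[j] <- ac$variance
    if (B > 0) {
      bb <- bootstrap_ce(cd, qaly_col = "qaly", cost_col = "total_cost",
                         covariates = covariates, B = max(100, b_each),
                         seed = bseeds[j])
      all_draws[[j]] <- bb$draws
    }
  }
  pooled_q <- pool_estimates(est_q, var_q)
  pooled_c <- pool_estimates(est_c, var_c)
  out <- list(pooled_qaly = pooled_q, pooled_cost = pooled_c,
              classification = classify_icer(pooled_c$estimate,
                                             pooled_q$estimate,
                                             granularity = granularity),
              m = m, seed = seed, per_imputation = data.frame(
                estimate_qaly = est_q, variance_qaly = var_q,
                estimate_cost = est_c, variance_cost = var_c))
  if (B > 0) {
    draws <- do.call(rbind, all_draws)
    out$draws <- draws
    out$ceac <- ceac(draws)
  }
  structure(out, class = "trial_cea")
}

#' @export
print.trial_cea <- function(x, ...) {
  cat(sprintf("Within-trial CEA (m = %d imputations)\n", x$m))
  cat(sprintf("  incremental cost: £%.0f (95%% CI £%.0f to £%.0f)\n",
              x$pooled_cost$estimate, x$pooled_cost$ci_low, x$pooled_cost$ci_high))
  cat(sprintf("  incremental QALYs: %.3f (95%% CI %.3f to %.3f)\n",
              x$pooled_qaly$estimate, x$pooled_qaly$ci_low, x$pooled_qaly$ci_high))
  cat("  "); print(x$classification)
  invisible(x)
}

#' Complete-case within-trial analysis
#'
#' Restricts to participants with fully observed utilities and period costs
#' and runs the same outcome construction and adjusted contrasts without
#' imputation.
#'
#' @inheritParams run_trial_cea
#' @return list with `delta_qaly`, `delta_cost` (each with variance and CI),
#'   `classification` and `n_complete`.
#' @export
run_complete_case_cea <- function(analysis, intervention_cost = 622,
                                  discount_rate = 0.035,
                                  covariates = c("age", "sex", "site", "u0",
                                                 "cost_base"),
                                  granularity = 1000,
                                  family = "gaussian_identity") {
  need <- c("u0", "u6", "u12", "u24", "cost_base", "cost_0_6", "cost_6_12",
            "cost_18_24")
  cc <- analysis[stats::complete.cases(analysis[need]), ]
  cd <- complete_outcomes(cc, intervention_cost, discount_rate)
  aq <- adjusted_increment(cd, "qaly", covariates = covariates, family = family)
  ac <- adjusted_increment(cd, "total_cost", covariates = covariates,
                           family = family)
  ciq <- aq$estimate + c(-1, 1) * stats::qnorm(0.975) * sqrt(aq$variance)
  cic <- ac$estimate + c(-1, 1) * stats::qnorm(0.975) * sqrt(ac$variance)
  list(delta_qaly = c(estimate = aq$estimate, ci_low = ciq[1], ci_high = ciq[2]),
       delta_cost = c(estimate = ac$estimate, ci_low = cic[1], ci_high = cic[2]),
       classification = classify_icer(ac$estimate, aq$estimate,
                                      granularity = granularity),
       n_complete = nrow(cc))
}

#' Empirical SPPB distribution at 24 months
#'
#' Histogram of observed 24-month SPPB scores per arm, as the Markov model's
#' start distributions.
#'
#' @param participants participant table with `arm` and `sppb_24m`.
#' @return list with `intervention` and `control`, each a length-13
#'   probability vector over SPPB 0-12.
#' @export
sppb_start_distributions <- function(participants) {
  one <- function(a) {
    x <- participants$sppb_24m[participants$arm == a]
    x <- x[!is.na(x)]
    if (!length(x)) stop("no observed 24-month SPPB in arm ", a, call. = FALSE)
    as.numeric(table(factor(x, levels = 0:12)) / length(x))
  }
  list(intervention = one("intervention"), control = one("control"))
}

#' Annual transition pairs from longitudinal SPPB observations
#'
#' Builds (current, next) SPPB pairs from the 0, 12 and 24-month
#' assessments (both gaps are one year), with age at the start of each
#' pair.
#'
#' @param participants participant table with `sppb_0m`, `sppb_12m`,
#'   `sppb_24m`, `age`, `sex`, `arm`.
#' @param arm which arm to extract (default control, matching the design
#'   that transition dynamics are fitted to control data only).
#' @return data frame with `sppb_from`, `sppb_to`, `age`, `sex`.
#' @export
sppb_transition_pairs <- function(participants, arm = "control") {
  pp <- participants[participants$arm == arm, ]
  p1 <- data.frame(sppb_from = pp$sppb_0m, sppb_to = pp$sppb_12m,
                   age = pp$age, sex = pp$sex)
  p2 <- data.frame(sppb_from = pp$sppb_12m, sppb_to = pp$sppb_24m,
                   age = pp$age + 1, sex = pp$sex)
  out <- rbind(p1, p2)
  out[stats::complete.cases(out), ]
}
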