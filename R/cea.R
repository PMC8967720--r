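#' Covariate-adjusted between-arm increment
#'
#' Fits a generalised linear model of a per-participant outcome (QALYs or
#' total cost) on trial arm and baseline covariates and returns the arm
#' contrast. For the identity link this is the arm coefficient; for the
#' gamma/log family it is the average marginal effect (mean difference of
#' fitted responses with everyone set to intervention versus control), with a
#' delta-method variance.
#'
#' @param data data frame, complete (post-imputation).
#' @param outcome name of the outcome column.
#' @param arm name of the arm column; coerced so that `arm_levels[2]` is the
#'   intervention.
#' @param covariates character vector of adjustment covariate names
#'   (stratification variables, baseline utility, baseline cost, ...).
#' @param family `"gaussian_identity"` (default) or `"gamma_log"`.
#' @param arm_levels length-2 character vector, `c(control, intervention)`.
#' @return list with `estimate` (intervention minus control) and `variance`.
#' @export
adjusted_increment <- function(data, outcome, arm = "arm",
                               covariates = character(),
                               family = c("gaussian_identity", "gamma_log"),
                               arm_levels = c("control", "intervention")) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(data), arm %in% names(data),
            all(covariates %in% names(data)))
  y <- data[[outcome]]
  if (anyNA(y)) stop("outcome contains missing values: impute first", call. = FALSE)
  a <- factor(data[[arm]], levels = arm_levels)
  if (anyNA(a)) stop("arm values outside arm_levels", call. = FALSE)
  df <- data.frame(.y = y, .arm = a, data[covariates], check.names = FALSE)
  rhs <- paste(c(".arm", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  if (family == "gaussian_identity") {
    fit <- stats::glm(fml, data = df, family = stats::gaussian())
    cname <- paste0(".arm", arm_levels[2])
    est <- unname(stats::coef(fit)[cname])
    v <- unname(stats::vcov(fit)[cname, cname])
    return(list(estimate = est, variance = v, family = family))
  }
  if (any(y <= 0)) {
    stop("gamma_log requires strictly positive outcomes; use gaussian_identity",
         call. = FALSE)
  }
  fit <- stats::glm(fml, data = df, family = stats::Gamma(link = "log"))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  d1 <- df; d1$.arm <- factor(arm_levels[2], levels = arm_levels)
  d0 <- df; d0$.arm <- factor(arm_levels[1], levels = arm_levels)
  X1 <- stats::model.matrix(stats::delete.response(stats::terms(fit)), d1)
  X0 <- stats::model.matrix(stats::delete.response(stats::terms(fit)), d0)
  mu1 <- exp(drop(X1 %*% beta))
  mu0 <- exp(drop(X0 %*% beta))
  est <- mean(mu1) - mean(mu0)
  grad <- colMeans(X1 * mu1) - colMeans(X0 * mu0)
  v <- drop(t(grad) %*% V %*% grad)
  list(estimate = est, variance = v, family = family)
}

#' Classify an incremental cost / incremental QALY pair
#'
#' Dominant means cheaper and more effective; dominated means more expensive
#' and less effective; otherwise the ICER (incremental cost per QALY) is
#' reported raw and rounded to a reporting granularity.
#'
#' @param delta_cost incremental cost, intervention minus control (GBP).
#' @param delta_qaly incremental QALYs.
#' @param granularity rounding granularity for the reported ICER in GBP
#'   (default 50; headline complete-case figures are conventionally rounded
#'   to 1000).
#' @return `ce_classification` object: `label` plus, when an ICER applies,
#'   `icer` (raw) and `icer_rounded`.
#' @examples
#' classify_icer(-103, 0.040)                     # dominant
#' classify_icer(297, 0.049, granularity = 1000)  # £6000 per QALY
#' @export
classify_icer <- function(delta_cost, delta_qaly, granularity = 50) {
  assert_scalar_num(delta_cost, "delta_cost")
  assert_scalar_num(delta_qaly, "delta_qaly")
  assert_scalar_num(granularity, "granularity", lower = 0)
  out <- list(delta_cost = delta_cost, delta_qaly = delta_qaly,
              icer = NA_real_, icer_rounded = NA_real_)
  if (delta_qaly == 0) {
    out$label <- if (delta_cost > 0) "dominated (no QALY gain)"
      else if (delta_cost < 0) "cost saving (no QALY change)"
      else "indifferent"
  } else if (delta_cost < 0 && delta_qaly > 0) {
    out$label <- "dominant"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    out$label <- "dominated"
  } else {
    out$label <- "ICER"
    out$icer <- delta_cost / delta_qaly
    out$icer_rounded <- if (granularity > 0) round(out$icer / granularity) * granularity
      else out$icer
  }
  structure(out, class = "ce_classification")
}

#' @export
print.ce_classification <- function(x, ...) {
  if (x$label == "ICER") {
    cat(sprintf("ICER: £%s per QALY (raw £%.1f)\n",
                format(x$icer_rounded, big.mark = ","), x$icer))
  } else {
    cat(x$label, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * delta_qaly - delta_cost`: the monetary value of the QALY gain at
#' a willingness-to-pay threshold, net of incremental cost.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qaly incremental QALYs.
#' @param lambda willingness to pay per QALY (GBP, `>= 0`).
#' @return net monetary benefit (GBP).
#' @examples
#' net_monetary_benefit(0, 0.040, 20000) # 800
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("'lambda' must be >= 0", call. = FALSE)
  lambda * delta_qaly - delta_cost
}

#' Bootstrap the joint distribution of incremental cost and QALYs
#'
#' Case resampling stratified by arm: each replicate resamples participants
#' with replacement within each arm and re-runs [adjusted_increment()] for
#' both outcomes. The percentile interval for the ICER is taken on the
#' net-benefit scale — the bounds are the willingness-to-pay values at which
#' the acceptability probability crosses 2.5% and 97.5% — which remains
#' well defined when the draw cloud spans quadrants.
#'
#' @param data complete participant-level data with QALY and cost columns.
#' @param qaly_col,cost_col outcome column names.
#' @param B bootstrap replicates (>= 100 enforced; >= 1000 recommended).
#' @param seed RNG seed.
#' @param lambda_max upper end of the threshold grid used for the
#'   net-benefit-scale ICER interval.
#' @inheritParams adjusted_increment
#' @return `ce_bootstrap` object: `draws` (B x 2 data frame of `delta_cost`,
#'   `delta_qaly`), point estimates, and `icer_ci`.
#' @export
bootstrap_ce <- function(data, qaly_col = "qaly", cost_col = "total_cost",
                         arm = "arm", covariates = character(), B = 1000,
                         seed = 1, arm_levels = c("control", "intervention"),
                         lambda_max = 100000) {
  if (B < 100) stop("B < 100 refused: percentile intervals are unstable", call. = FALSE)
  idx_by_arm <- split(seq_len(nrow(data)), factor(data[[arm]], levels = arm_levels))
  point_q <- adjusted_increment(data, qaly_col, arm, covariates,
                                arm_levels = arm_levels)
  point_c <- adjusted_increment(data, cost_col, arm, covariates,
                                arm_levels = arm_levels)
  set.seed(seed)
  draws <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_arm, function(ii) ii[sample.int(length(ii),
                                                                 length(ii),
                                                                 replace = TRUE)]),
                   use.names = FALSE)
    dd <- data[take, , drop = FALSE]
    draws[b, 1] <- adjusted_increment(dd, cost_col, arm, covariates,
                                      arm_levels = arm_levels)$estimate
    draws[b, 2] <- adjusted_increment(dd, qaly_col, arm, covariates,
                                      arm_levels = arm_levels)$estimate
  }
  draws <- data.frame(delta_cost = draws[, 1], delta_qaly = draws[, 2])
  grid <- seq(0, lambda_max, by = 50)
  pce <- vapply(grid, function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0),
                numeric(1))
  icer_ci <- c(lower = if (any(pce >= 0.975)) grid[which(pce >= 0.975)[1]] else NA_real_,
               upper = if (any(pce >= 0.025)) grid[which(pce >= 0.025)[1]] else NA_real_)
  structure(list(draws = draws,
                 delta_cost = point_c$estimate, delta_qaly = point_q$estimate,
                 icer_ci = icer_ci, B = B, seed = seed),
            class = "ce_bootstrap")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of joint
#' (incremental cost, incremental QALY) draws with positive net monetary
#' benefit.
#'
#' @param draws data frame with columns `delta_cost` and `delta_qaly`
#'   (bootstrap or PSA draws), or a [bootstrap_ce()] result.
#' @param lambda_grid strictly increasing willingness-to-pay grid (GBP/QALY);
#'   default 0 to 50,000 in steps of 500.
#' @return `ceac_curve` object: data frame with columns `lambda`,
#'   `probability`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 50000, by = 500)) {
  if (inherits(draws, "ce_bootstrap")) draws <- draws$draws
  if (!nrow(draws)) stop("no draws supplied", call. = FALSE)
  if (!length(lambda_grid)) stop("empty willingness-to-pay grid", call. = FALSE)
  if (is.unsorted(lambda_grid, strictly = TRUE)) {
    stop("'lambda_grid' must be strictly increasing", call. = FALSE)
  }
  p <- vapply(lambda_grid,
              function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0),
              numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = p),
            class = c("ceac_curve", "data.frame"))
}
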