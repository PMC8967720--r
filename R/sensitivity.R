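#' Parameter distribution for probabilistic sensitivity analysis
#'
#' Families follow decision-modelling convention: beta for utilities
#' (support bounded above by 1, optionally rescaled to `[min, max]`), gamma
#' or lognormal for costs (non-negative support), dirichlet for probability
#' vectors, normal for unbounded parameters, and fixed for parameters held
#' at a point value.
#'
#' @param name parameter name (must be understood by the draw applier, see
#'   [apply_psa_draw()]).
#' @param family one of `"fixed"`, `"normal"`, `"beta"`, `"gamma"`,
#'   `"lognormal"`, `"dirichlet"`.
#' @param ... hyperparameters: `value` (fixed); `mean`, `sd` (normal);
#'   `shape1`, `shape2` and optional `min`, `max` (beta); `shape`, `rate`
#'   (gamma); `meanlog`, `sdlog` (lognormal); `alpha` vector (dirichlet).
#' @return `parameter_distribution` object.
#' @export
parameter_distribution <- function(name, family = c("fixed", "normal", "beta",
                                                    "gamma", "lognormal",
                                                    "dirichlet"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  chk <- function(fields) {
    miss <- setdiff(fields, names(hp))
    if (length(miss)) stop(sprintf("%s distribution '%s' needs: %s", family,
                                   name, paste(miss, collapse = ", ")),
                           call. = FALSE)
  }
  switch(family,
    fixed     = chk("value"),
    normal    = { chk(c("mean", "sd")); stopifnot(hp$sd >= 0) },
    beta      = { chk(c("shape1", "shape2")); stopifnot(hp$shape1 > 0, hp$shape2 > 0) },
    gamma     = { chk(c("shape", "rate")); stopifnot(hp$shape > 0, hp$rate > 0) },
    lognormal = { chk(c("meanlog", "sdlog")); stopifnot(hp$sdlog >= 0) },
    dirichlet = { chk("alpha"); stopifnot(all(hp$alpha > 0)) }
  )
  structure(list(name = name, family = family, hyper = hp),
            class = "parameter_distribution")
}

# internal: one draw from a parameter_distribution
draw_parameter <- function(pd) {
  hp <- pd$hyper
  switch(pd$family,
    fixed     = hp$value,
    normal    = stats::rnorm(1, hp$mean, hp$sd),
    beta      = {
      x <- stats::rbeta(1, hp$shape1, hp$shape2)
      lo <- if (is.null(hp$min)) 0 else hp$min
      hi <- if (is.null(hp$max)) 1 else hp$max
      lo + (hi - lo) * x
    },
    gamma     = stats::rgamma(1, shape = hp$shape, rate = hp$rate),
    lognormal = stats::rlnorm(1, hp$meanlog, hp$sdlog),
    dirichlet = {
      g <- stats::rgamma(length(hp$alpha), shape = hp$alpha, rate = 1)
      g / sum(g)
    }
  )
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' @param distributions list of [parameter_distribution()] objects.
#' @param n number of parameter sets (`>= 1`).
#' @param seed RNG seed (reproducible).
#' @return list of `n` named lists of sampled values.
#' @export
sample_parameters <- function(distributions, n, seed = 1) {
  stopifnot(n >= 1, length(distributions) >= 1)
  nm <- vapply(distributions, function(d) d$name, character(1))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stats::setNames(lapply(distributions, draw_parameter), nm)
  })
}

#' Base configuration of the lifetime decision model
#'
#' Bundles everything [lifetime_cea()] needs so the sensitivity module can
#' re-evaluate the model under perturbed parameters.
#'
#' @param trial_delta_cost,trial_delta_qaly within-trial increments.
#' @param start_int,start_ctrl per-arm SPPB start distributions.
#' @param model,values,life_table,start_age,sex as in [lifetime_cea()].
#' @param discount_rate annual rate.
#' @param half_cycle logical.
#' @return list of class `model_base`.
#' @export
model_base <- function(trial_delta_cost, trial_delta_qaly, start_int,
                       start_ctrl, model, values, life_table, start_age, sex,
                       discount_rate = 0.035, half_cycle = FALSE) {
  structure(list(trial_delta_cost = trial_delta_cost,
                 trial_delta_qaly = trial_delta_qaly,
                 start_int = start_int, start_ctrl = start_ctrl,
                 model = model, values = values, life_table = life_table,
                 start_age = start_age, sex = sex,
                 discount_rate = discount_rate, half_cycle = half_cycle),
            class = "model_base")
}

#' Apply a sampled parameter set to the base model
#'
#' Recognised parameter names: `utility_intercept`/`utility_slope` (state
#' utility line over SPPB 0-12), `cost_intercept`/`cost_slope` (state cost
#' line), `utility_mult`/`cost_mult` (multipliers on the base state values),
#' `mortality_mult` (multiplier on all life-table death probabilities),
#' `trial_delta_cost`/`trial_delta_qaly` (replacement trial-phase
#' increments), `start_int`/`start_ctrl` (replacement 13-vector start
#' distributions, e.g. dirichlet draws). Values are applied without
#' clamping; implausible draws are caught downstream and rejected.
#'
#' @param base a [model_base()].
#' @param draw named list of parameter values.
#' @return modified `model_base`.
#' @export
apply_psa_draw <- function(base, draw) {
  known <- c("utility_intercept", "utility_slope", "cost_intercept",
             "cost_slope", "utility_mult", "cost_mult", "mortality_mult",
             "trial_delta_cost", "trial_delta_qaly", "start_int", "start_ctrl")
  bad <- setdiff(names(draw), known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  b <- base
  s <- 0:12
  u <- b$values$utility
  cc <- b$values$annual_cost
  if (!is.null(draw$utility_intercept) || !is.null(draw$utility_slope)) {
    a0 <- if (is.null(draw$utility_intercept)) u[1] else draw$utility_intercept
    a1 <- if (is.null(draw$utility_slope)) (u[13] - u[1]) / 12 else draw$utility_slope
    u <- a0 + a1 * s
  }
  if (!is.null(draw$cost_intercept) || !is.null(draw$cost_slope)) {
    c0 <- if (is.null(draw$cost_intercept)) cc[1] else draw$cost_intercept
    c1 <- if (is.null(draw$cost_slope)) (cc[13] - cc[1]) / 12 else draw$cost_slope
    cc <- c0 + c1 * s
  }
  if (!is.null(draw$utility_mult)) u <- u * draw$utility_mult
  if (!is.null(draw$cost_mult)) cc <- cc * draw$cost_mult
  b$values <- list(annual_cost = cc, utility = u) # validated at evaluation
  if (!is.null(draw$mortality_mult)) {
    b$life_table$qx <- b$life_table$qx * draw$mortality_mult
  }
  for (f in c("trial_delta_cost", "trial_delta_qaly", "start_int", "start_ctrl")) {
    if (!is.null(draw[[f]])) b[[f]] <- draw[[f]]
  }
  b
}

# internal: evaluate the lifetime model for a (possibly perturbed) base;
# returns NULL for draws violating structural constraints
eval_model_base <- function(b) {
  ok <- all(b$values$utility <= 1 + 1e-9) && all(b$values$annual_cost >= 0) &&
    all(b$life_table$qx >= 0 & b$life_table$qx <= 1) &&
    all(b$start_int >= 0) && all(b$start_ctrl >= 0) &&
    abs(sum(b$start_int) - 1) < 1e-6 && abs(sum(b$start_ctrl) - 1) < 1e-6
  if (!ok) return(NULL)
  vals <- state_values(b$values$annual_cost, b$values$utility)
  lifetime_cea(b$trial_delta_cost, b$trial_delta_qaly, b$start_int,
               b$start_ctrl, b$model, vals, b$life_table, b$start_age, b$sex,
               discount_rate = b$discount_rate, half_cycle = b$half_cycle)
}

#' Probabilistic sensitivity analysis of the lifetime model
#'
#' Samples `n` parameter sets, re-runs the full Markov cost-effectiveness
#' analysis for each, and summarises the joint draws with percentile
#' credible intervals and a model-based acceptability curve. Draws that
#' produce structurally invalid inputs (utility above 1, negative cost,
#' death probability outside `[0,1]`, invalid start distribution) are
#' rejected and counted, never clamped.
#'
#' @param base a [model_base()].
#' @param distributions list of [parameter_distribution()]s.
#' @param n draws (default 5000).
#' @param seed RNG seed.
#' @param lambda_grid willingness-to-pay grid for the CEAC.
#' @param applier function mapping (base, draw) to a modified base; default
#'   [apply_psa_draw()].
#' @return `psa_result`: `draws` data frame, means, 95% credible intervals,
#'   `ceac` curve and `n_rejected`.
#' @export
psa_run <- function(base, distributions, n = 5000, seed = 1,
                    lambda_grid = seq(0, 50000, by = 500),
                    applier = apply_psa_draw) {
  sets <- sample_parameters(distributions, n, seed)
  dc <- dq <- rep(NA_real_, n)
  rejected <- 0L
  for (i in seq_len(n)) {
    res <- eval_model_base(applier(base, sets[[i]]))
    if (is.null(res)) { rejected <- rejected + 1L; next }
    dc[i] <- res$delta_cost
    dq[i] <- res$delta_qaly
  }
  keep <- !is.na(dc)
  if (!any(keep)) stop("all PSA draws rejected", call. = FALSE)
  if (rejected > 0) {
    message(sprintf("psa_run: %d of %d draws rejected (invalid model inputs)",
                    rejected, n))
  }
  draws <- data.frame(delta_cost = dc[keep], delta_qaly = dq[keep])
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(draws = draws,
                 mean_delta_cost = mean(draws$delta_cost),
                 mean_delta_qaly = mean(draws$delta_qaly),
                 ci_cost = qs(draws$delta_cost),
                 ci_qaly = qs(draws$delta_qaly),
                 ceac = ceac(draws, lambda_grid),
                 n = n, n_rejected = rejected, seed = seed),
            class = "psa_result")
}

#' Deterministic one-way sensitivity analysis (tornado)
#'
#' Re-evaluates the deterministic lifetime model at the low and high end of
#' each parameter's range, holding every other parameter at base, and ranks
#' parameters by the absolute swing in net monetary benefit.
#'
#' @param base a [model_base()].
#' @param ranges data frame with columns `parameter`, `base`, `low`, `high`
#'   (each range must bracket the base value).
#' @param lambda willingness-to-pay threshold at which net monetary benefit
#'   is evaluated (default 20000 GBP/QALY).
#' @param applier as in [psa_run()].
#' @return data frame (`parameter`, `low`, `high`, `nmb_low`, `nmb_high`,
#'   `swing`) sorted by decreasing swing.
#' @export
one_way <- function(base, ranges, lambda = 20000, applier = apply_psa_draw) {
  stopifnot(all(c("parameter", "base", "low", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$base | ranges$high < ranges$base)) {
    stop("each range must bracket the base value", call. = FALSE)
  }
  nmb_at <- function(param, value) {
    d <- stats::setNames(list(value), param)
    res <- eval_model_base(applier(base, d))
    if (is.null(res)) stop("bound produces invalid model inputs: ", param,
                           call. = FALSE)
    net_monetary_benefit(res$delta_cost, res$delta_qaly, lambda)
  }
  lo <- mapply(nmb_at, ranges$parameter, ranges$low)
  hi <- mapply(nmb_at, ranges$parameter, ranges$high)
  out <- data.frame(parameter = ranges$parameter,
                    low = ranges$low, high = ranges$high,
                    nmb_low = unname(lo), nmb_high = unname(hi),
                    swing = abs(unname(hi) - unname(lo)))
  out[order(-out$swing), , drop = FALSE]
}
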