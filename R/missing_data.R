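#' Multiple imputation by predictive mean matching
#'
#' Chained-equations imputation of numeric variables. Each sweep regresses
#' every incomplete variable on the predictors plus the current completed
#' values of the other incomplete variables, draws regression parameters from
#' their approximate posterior (normal for coefficients, scaled
#' inverse-chi-squared for the residual variance), and replaces each missing
#' value with the *observed* value of one of the `k_donors` donors whose
#' predicted means are closest to the recipient's predicted mean (donor
#' predictions use the posterior mode, recipient predictions the posterior
#' draw). Imputed values are therefore always members of the observed
#' support.
#'
#' @param data data frame. Fully observed columns of any type act as
#'   predictors; incomplete columns to impute must be numeric.
#' @param m number of imputed datasets (default 50).
#' @param k_donors donor-pool size (default 5).
#' @param iterations chained-equation sweeps per imputation (default 10).
#' @param seed master seed; one sub-stream is spawned per imputation, so the
#'   result is reproducible and individual imputations are independent.
#' @param impute_vars columns to impute; default: all columns containing
#'   `NA`.
#' @param predictors fully observed columns used in every imputation model;
#'   default: all complete columns.
#' @return list of `m` completed data frames (class `pmm_imputations`);
#'   observed cells are untouched.
#' @export
pmm_impute <- function(data, m = 50, k_donors = 5, iterations = 10, seed = 1,
                       impute_vars = NULL, predictors = NULL) {
  stopifnot(is.data.frame(data), m >= 2, k_donors >= 1, iterations >= 1)
  if (is.null(impute_vars)) {
    impute_vars <- names(data)[vapply(data, anyNA, logical(1))]
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[!vapply(data, anyNA, logical(1))],
                          impute_vars)
  }
  if (!length(predictors)) {
    stop("at least one fully observed predictor is required", call. = FALSE)
  }
  for (v in impute_vars) {
    if (all(is.na(data[[v]]))) {
      stop("variable has no observed values: ", v, call. = FALSE)
    }
    if (!is.numeric(data[[v]])) {
      stop("imputed variable must be numeric: ", v, call. = FALSE)
    }
  }
  impute_vars <- impute_vars[vapply(impute_vars, function(v) anyNA(data[[v]]),
                                    logical(1))]
  if (!length(impute_vars)) {
    out <- replicate(m, data, simplify = FALSE)
    return(structure(out, class = "pmm_imputations", seed = seed))
  }

  mis_idx <- lapply(impute_vars, function(v) which(is.na(data[[v]])))
  names(mis_idx) <- impute_vars
  seeds <- spawn_seeds(seed, m)

  one_imputation <- function(s) {
    set.seed(s)
    comp <- data
    for (v in impute_vars) { # initial fill: random draw from observed values
      obs <- comp[[v]][!is.na(comp[[v]])]
      comp[[v]][mis_idx[[v]]] <- sample(obs, length(mis_idx[[v]]), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in impute_vars) {
        rhs <- c(predictors, setdiff(impute_vars, v))
        X <- stats::model.matrix(~ ., data = comp[rhs])
        y <- data[[v]]
        oi <- which(!is.na(y))
        mi <- mis_idx[[v]]
        draw <- bayes_lm_draw(X[oi, , drop = FALSE], y[oi])
        yhat_obs <- drop(X[oi, draw$keep, drop = FALSE] %*% draw$beta_hat)
        yhat_mis <- drop(X[mi, draw$keep, drop = FALSE] %*% draw$beta_draw)
        comp[[v]][mi] <- pmm_match(yhat_obs, y[oi], yhat_mis, k_donors)
      }
    }
    comp
  }
  out <- lapply(seeds, one_imputation)
  structure(out, class = "pmm_imputations", seed = seed)
}

# internal: posterior draw for a linear model; drops aliased columns
bayes_lm_draw <- function(X, y) {
  qrx <- qr(X)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(X, y)
  beta_hat <- fit$coefficients
  df <- max(length(y) - qrx$rank, 1L)
  rss <- sum(fit$residuals^2)
  sigma2 <- if (rss < 1e-12) 0 else rss / stats::rchisq(1, df)
  xtx_inv <- chol2inv(qr.R(qr(X)))
  # symmetrise against rounding before factorisation
  cv <- sigma2 * (xtx_inv + t(xtx_inv)) / 2
  beta_draw <- beta_hat + drop(crossprod(chol(cv + diag(1e-12, ncol(X))),
                                         stats::rnorm(ncol(X))))
  list(beta_hat = beta_hat, beta_draw = beta_draw, keep = keep)
}

# internal: for each recipient predicted mean, sample one of the k nearest
# donors (by predicted mean) and return that donor's observed value
pmm_match <- function(yhat_obs, y_obs, yhat_mis, k) {
  k <- min(k, length(y_obs))
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(k)]
    y_obs[pool[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; total
#' variance is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance. Degrees of freedom follow Barnard-Rubin when
#' a finite complete-data df is supplied, otherwise the classical
#' `(m-1)(1 + 1/riv)^2`.
#'
#' @param estimates numeric vector of per-imputation point estimates
#'   (length `m >= 2`).
#' @param variances per-imputation sampling variances (same length, `>= 0`).
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @param conf confidence level for the t interval (default 0.95).
#' @return `pooled_estimate` object: estimate, within/between/total
#'   variance, df, and confidence limits.
#' @export
pool_estimates <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations", call. = FALSE)
  stopifnot(length(variances) == m, all(variances >= 0), !anyNA(estimates))
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  total <- ubar + (1 + 1 / m) * b
  if (b <= 0) {
    df <- Inf
  } else if (ubar <= 0) {
    df <- m - 1
  } else {
    riv <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / riv)^2
    if (is.finite(dfcom)) {
      lam <- riv / (1 + riv)
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lam)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  half <- stats::qt(1 - (1 - conf) / 2, df) * sqrt(total)
  structure(list(estimate = qbar, within_variance = ubar,
                 between_variance = b, total_variance = total,
                 df = df, ci_low = qbar - half, ci_high = qbar + half,
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (95%% CI %.4f to %.4f), m = %d, total var %.5g\n",
              x$estimate, x$ci_low, x$ci_high, x$m, x$total_variance))
  invisible(x)
}
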