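# brute-force helper: NMB of the lifetime model at one parameter value
nmb_param <- function(base, param, value) {
  b2 <- apply_psa_draw(base, setNames(list(value), param))
  vals <- state_values(b2$values$annual_cost, b2$values$utility)
  r <- lifetime_cea(b2$trial_delta_cost, b2$trial_delta_qaly, b2$start_int,
                    b2$start_ctrl, b2$model, vals, b2$life_table,
                    b2$start_age, b2$sex)
  net_monetary_benefit(r$delta_cost, r$delta_qaly, 20000)
}

# shared deterministic base model for the sensitivity tests
sens_base <- local({
  b <- NULL
  function() {
    if (is.null(b)) {
      m <- fit_transition_model(simulate_ordinal_pairs(3000, seed = 17))
      vals <- state_values(4000 - 150 * (0:12), pmin(1, 0.45 + 0.035 * (0:12)))
      hi <- c(rep(0, 6), rep(1 / 7, 7))
      lo <- c(rep(1 / 7, 7), rep(0, 6))
      b <<- model_base(-103, 0.040, hi, lo, m, vals, generate_life_table(),
                       75, "female")
    }
    b
  }
})

test_that("sample_parameters: fixed sets repeat, moments and simplex constraints hold", {
  dists <- list(parameter_distribution("a", "fixed", value = 3),
                parameter_distribution("b", "fixed", value = -1))
  sets <- sample_parameters(dists, 5, seed = 1)
  expect_true(all(vapply(sets, function(s) identical(s, list(a = 3, b = -1)),
                         logical(1))))
  # beta moment check
  bsets <- sample_parameters(list(parameter_distribution("u", "beta",
                                                         shape1 = 8, shape2 = 2)),
                             10000, seed = 2)
  u <- vapply(bsets, function(s) s$u, numeric(1))
  se <- sqrt(0.8 * 0.2 / (8 + 2 + 1)) / sqrt(10000)
  expect_lt(abs(mean(u) - 0.8), 3 * se)
  # dirichlet draws are probability vectors
  dsets <- sample_parameters(list(parameter_distribution("p", "dirichlet",
                                                         alpha = rep(2, 13))),
                             50, seed = 3)
  for (s in dsets) {
    expect_equal(sum(s$p), 1, tolerance = 1e-12)
    expect_true(all(s$p >= 0))
  }
  expect_error(parameter_distribution("x", "beta", shape1 = 2), "shape2")
})

test_that("psa_run is deterministic and collapses to the deterministic result", {
  base <- sens_base()
  dists <- list(parameter_distribution("utility_slope", "fixed", value = 0.035),
                parameter_distribution("cost_slope", "fixed", value = -150))
  ps <- psa_run(base, dists, n = 20, seed = 4)
  expect_equal(diff(ps$ci_qaly), 0, tolerance = 1e-12) # width-0 credible interval
  det <- lifetime_cea(base$trial_delta_cost, base$trial_delta_qaly,
                      base$start_int, base$start_ctrl, base$model, base$values,
                      base$life_table, base$start_age, base$sex)
  expect_equal(ps$mean_delta_qaly, det$delta_qaly, tolerance = 1e-9)
  expect_equal(ps$mean_delta_cost, det$delta_cost, tolerance = 1e-9)
  # reproducibility
  d2 <- list(parameter_distribution("utility_slope", "normal", mean = 0.035,
                                    sd = 0.004))
  a <- psa_run(base, d2, n = 60, seed = 9)
  b <- psa_run(base, d2, n = 60, seed = 9)
  expect_identical(a$draws, b$draws)
})

test_that("psa percentiles match an analytic linear case", {
  base <- sens_base()
  # post-trial QALY delta is linear in utility_slope with the other
  # parameters fixed; slope of that line measured from two evaluations
  ev <- function(s) {
    eval_fn <- function(v) {
      b2 <- apply_psa_draw(base, list(utility_slope = v))
      vals <- state_values(b2$values$annual_cost, b2$values$utility)
      lifetime_cea(b2$trial_delta_cost, b2$trial_delta_qaly, b2$start_int,
                   b2$start_ctrl, b2$model, vals, b2$life_table, b2$start_age,
                   b2$sex)$delta_qaly
    }
    eval_fn(s)
  }
  q0 <- ev(0.030); q1 <- ev(0.040)
  k <- (q1 - q0) / 0.010 # QALY delta per unit slope
  ps <- psa_run(base, list(parameter_distribution("utility_slope", "normal",
                                                  mean = 0.035, sd = 0.003)),
                n = 4000, seed = 5)
  expect_equal(ps$n_rejected, 0)
  mu <- q0 + k * (0.035 - 0.030)
  mc_se <- abs(k) * 0.003 / sqrt(4000)
  expect_lt(abs(ps$mean_delta_qaly - mu), 3 * mc_se)
  width_true <- 2 * qnorm(0.975) * abs(k) * 0.003
  expect_lt(abs((ps$ci_qaly[2] - ps$ci_qaly[1]) - width_true), 0.1 * width_true)
  # PSA CEAC obeys lambda monotonicity when QALY gains are non-negative
  if (all(ps$draws$delta_qaly >= 0)) {
    expect_true(all(diff(ps$ceac$probability) >= 0))
  }
})

test_that("invalid draws are rejected and logged, not clamped", {
  base <- sens_base()
  # slope large enough that utility at SPPB 12 exceeds 1 for most draws
  dists <- list(parameter_distribution("utility_slope", "normal",
                                       mean = 0.046, sd = 0.001))
  expect_message(ps <- psa_run(base, dists, n = 50, seed = 6), "rejected")
  expect_gt(ps$n_rejected, 0)
  expect_true(all(ps$draws$delta_qaly > 0 | ps$draws$delta_qaly <= 0)) # finite
})

test_that("one_way: zero-influence parameters, linearity, and brute-force ordering", {
  base <- sens_base()
  rng <- data.frame(parameter = c("mortality_mult", "cost_intercept",
                                  "utility_slope"),
                    base = c(1, 4000, 0.035),
                    low = c(1, 3000, 0.02),
                    high = c(1, 5000, 0.045))
  tor <- one_way(base, rng)
  # degenerate range (no influence exercised) -> exactly zero swing
  expect_equal(tor$swing[tor$parameter == "mortality_mult"], 0)
  # NMB is linear in cost_intercept: swing = |slope| * width exactly
  nmb_at <- function(ci) {
    b2 <- apply_psa_draw(base, list(cost_intercept = ci))
    vals <- state_values(b2$values$annual_cost, b2$values$utility)
    r <- lifetime_cea(b2$trial_delta_cost, b2$trial_delta_qaly, b2$start_int,
                      b2$start_ctrl, b2$model, vals, b2$life_table,
                      b2$start_age, b2$sex)
    net_monetary_benefit(r$delta_cost, r$delta_qaly, 20000)
  }
  slope <- (nmb_at(4001) - nmb_at(4000))
  expect_equal(tor$swing[tor$parameter == "cost_intercept"],
               abs(slope) * 2000, tolerance = 1e-6 * max(1, abs(slope) * 2000))
  # ordering matches brute-force evaluation at all bounds
  brute <- vapply(seq_len(nrow(rng)), function(i) {
    abs(nmb_param(base, rng$parameter[i], rng$high[i]) -
          nmb_param(base, rng$parameter[i], rng$low[i]))
  }, numeric(1))
  expect_equal(tor$parameter, rng$parameter[order(-brute)])
  # invariant under parameter reordering
  tor2 <- one_way(base, rng[c(3, 1, 2), ])
  expect_equal(tor2$parameter, tor$parameter)
  expect_error(one_way(base, data.frame(parameter = "utility_slope", base = 0.035,
                                        low = 0.04, high = 0.05)), "bracket")
})
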