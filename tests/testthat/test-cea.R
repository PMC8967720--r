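make_arm_data <- function(n = 200, effect = 0.04, sd = 0, seed = 1) {
  set.seed(seed)
  arm <- rep(c("control", "intervention"), length.out = n)
  x <- rnorm(n)
  data.frame(arm = arm, x = x,
             y = effect * (arm == "intervention") + 0.5 * x + rnorm(n, 0, sd))
}

test_that("adjusted_increment recovers a noiseless arm effect exactly", {
  d <- make_arm_data(effect = 0.04, sd = 0)
  fit <- adjusted_increment(d, "y", covariates = "x")
  expect_equal(fit$estimate, 0.04, tolerance = 1e-10)
  # identical outcomes in both arms: estimate 0
  d$y <- 3 * d$x
  expect_equal(adjusted_increment(d, "y", covariates = "x")$estimate, 0,
               tolerance = 1e-10)
})

test_that("adjusted_increment estimates a stochastic effect within 2 SE", {
  d <- make_arm_data(n = 777, effect = 0.04, sd = 0.1, seed = 1)
  fit <- adjusted_increment(d, "y", covariates = "x")
  expect_lt(abs(fit$estimate - 0.04), 2 * sqrt(fit$variance))
})

test_that("gamma_log returns an average marginal effect and rejects non-positive outcomes", {
  set.seed(4)
  n <- 2000
  arm <- rep(c("control", "intervention"), length.out = n)
  x <- runif(n)
  mu <- exp(6 + 0.2 * (arm == "intervention") + 0.3 * x)
  d <- data.frame(arm = arm, x = x, y = rgamma(n, shape = 5, rate = 5 / mu))
  fit <- adjusted_increment(d, "y", covariates = "x", family = "gamma_log")
  truth <- mean(exp(6 + 0.2 + 0.3 * x)) - mean(exp(6 + 0.3 * x))
  expect_lt(abs(fit$estimate - truth), 3 * sqrt(fit$variance))
  d$y[1] <- 0
  expect_error(adjusted_increment(d, "y", covariates = "x", family = "gamma_log"),
               "gaussian_identity")
})

test_that("classify_icer reproduces the headline classifications", {
  expect_equal(classify_icer(-103, 0.040)$label, "dominant")
  cc <- classify_icer(297, 0.049, granularity = 1000)
  expect_equal(cc$label, "ICER")
  expect_equal(cc$icer_rounded, 6000)
  expect_equal(cc$icer, 297 / 0.049)
  expect_equal(classify_icer(0, 0)$label, "indifferent")
  expect_equal(classify_icer(100, 0)$label, "dominated (no QALY gain)")
  expect_equal(classify_icer(100, -0.01)$label, "dominated")
  # granularity 50 convention
  expect_equal(classify_icer(620, 0.04, granularity = 50)$icer_rounded, 15500)
})

test_that("negating both deltas swaps dominant and dominated", {
  set.seed(2)
  for (i in 1:20) {
    dc <- runif(1, -500, 500)
    dq <- runif(1, -0.1, 0.1)
    a <- classify_icer(dc, dq)$label
    b <- classify_icer(-dc, -dq)$label
    if (a == "dominant") expect_equal(b, "dominated")
    if (a == "dominated") expect_equal(b, "dominant")
    if (a == "ICER") expect_equal(b, "ICER") # same ratio, opposite quadrant pair
  }
})

test_that("net monetary benefit matches the threshold arithmetic", {
  expect_equal(net_monetary_benefit(0, 0.040, 20000), 800)
  expect_equal(net_monetary_benefit(0, 0.040, 30000), 1200)
  expect_equal(net_monetary_benefit(500, 0, 25000), -500)
  expect_error(net_monetary_benefit(0, 0.04, -1), "lambda")
})

test_that("bootstrap_ce is deterministic, degenerate on constant data, and refuses tiny B", {
  d <- make_arm_data(n = 60, effect = 0.05, sd = 0.1, seed = 3)
  d$cost <- 100 * (d$arm == "intervention") + 20 * d$x + rnorm(60, 0, 30)
  a <- bootstrap_ce(d, qaly_col = "y", cost_col = "cost", covariates = "x",
                    B = 150, seed = 7)
  b <- bootstrap_ce(d, qaly_col = "y", cost_col = "cost", covariates = "x",
                    B = 150, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_error(bootstrap_ce(d, qaly_col = "y", cost_col = "cost", B = 50),
               "refused|unstable")
  # every participant identical within arm -> all draws identical
  dd <- data.frame(arm = rep(c("control", "intervention"), each = 10),
                   y = rep(c(0.5, 0.54), each = 10),
                   cost = rep(c(1000, 900), each = 10))
  bb <- bootstrap_ce(dd, qaly_col = "y", cost_col = "cost", B = 120, seed = 1)
  expect_equal(max(abs(bb$draws$delta_qaly - 0.04)), 0, tolerance = 1e-10)
  expect_equal(max(abs(bb$draws$delta_cost + 100)), 0, tolerance = 1e-10)
})

test_that("bootstrap percentile interval covers the true QALY effect in >= 90/100 repetitions", {
  cover <- 0
  for (rep_ in 1:100) {
    d <- make_arm_data(n = 150, effect = 0.04, sd = 0.12, seed = 5000 + rep_)
    bb <- bootstrap_ce(d, qaly_col = "y", cost_col = "y", covariates = "x",
                       B = 200, seed = rep_)
    ci <- quantile(bb$draws$delta_qaly, c(0.025, 0.975))
    if (ci[1] <= 0.04 && ci[2] >= 0.04) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("bootstrap mean tracks the point estimate", {
  d <- make_arm_data(n = 300, effect = 0.04, sd = 0.1, seed = 9)
  bb <- bootstrap_ce(d, qaly_col = "y", cost_col = "y", covariates = "x",
                     B = 500, seed = 2)
  mc_se <- sd(bb$draws$delta_qaly) / sqrt(nrow(bb$draws))
  expect_lt(abs(mean(bb$draws$delta_qaly) - bb$delta_qaly), 3 * mc_se)
})

test_that("ceac matches brute-force counting and its limits", {
  draws <- data.frame(delta_cost = c(100, -50, 200, -10),
                      delta_qaly = c(0.01, -0.001, 0.004, 0.02))
  cv <- ceac(draws, lambda_grid = c(0, 20000))
  # lambda = 0: fraction cost saving = 2/4
  expect_equal(cv$probability[1], 0.5)
  # lambda = 20000 by enumeration: NB = (100, 30, -120, 410) -> 3/4
  expect_equal(cv$probability[2], 0.75)
  # all draws dominant -> probability 1 everywhere
  dom <- data.frame(delta_cost = c(-10, -20), delta_qaly = c(0.01, 0.02))
  expect_true(all(ceac(dom)$probability == 1))
  expect_error(ceac(draws, lambda_grid = numeric(0)), "grid")
  expect_error(ceac(draws, lambda_grid = c(10, 5)), "increasing")
})

test_that("ceac is monotone in lambda when all QALY gains are non-negative", {
  set.seed(8)
  draws <- data.frame(delta_cost = rnorm(500, 0, 300),
                      delta_qaly = abs(rnorm(500, 0.04, 0.02)))
  cv <- ceac(draws)
  expect_true(all(diff(cv$probability) >= 0))
  # limit: fraction of draws with positive QALY gain
  expect_equal(ceac(draws, lambda_grid = c(0, 1e9))$probability[2],
               mean(draws$delta_qaly > 0))
})
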