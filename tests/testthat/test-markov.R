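test_that("ordinal transition model recovers known coefficients within 2 SE (n = 5000)", {
  truth <- c(sppb_from = 0.9, age = -0.03, sexmale = -0.4)
  pairs <- simulate_ordinal_pairs(5000, truth[1], truth[2], truth[3], seed = 42)
  m <- fit_transition_model(pairs)
  cf <- m$fit$coefficients
  se <- sqrt(diag(vcov(m$fit)))[names(cf)]
  for (nm in names(truth)) {
    expect_lt(abs(cf[[nm]] - truth[[nm]]), 2 * se[[nm]])
  }
})

test_that("manual ordinal probabilities agree with polr predict", {
  pairs <- simulate_ordinal_pairs(2000, seed = 7)
  m <- fit_transition_model(pairs)
  nd <- data.frame(sppb_from = 0:12, age = 80,
                   sex = factor("male", levels = c("female", "male")))
  p_ref <- predict(m$fit, newdata = nd, type = "probs")
  p_mine <- t(vapply(0:12, function(s) predict_transition(m, s, 80, "male"),
                     numeric(13)))
  expect_equal(unname(p_mine[, as.character(m$levels)]), unname(p_ref),
               tolerance = 1e-12)
})

test_that("a static panel predicts persistence; predictions always normalise", {
  pairs <- simulate_ordinal_pairs(1500, seed = 3)
  pairs$sppb_to <- pairs$sppb_from # SPPB never changes
  m <- fit_transition_model(pairs)
  for (s in c(0, 4, 8, 12)) {
    p <- predict_transition(m, s, 75, "female")
    expect_equal(unname(which.max(p)) - 1, s) # modal next state = current
  }
  m2 <- fit_transition_model(simulate_ordinal_pairs(1000, seed = 5))
  for (s in 0:12) {
    expect_equal(sum(predict_transition(m2, s, 70, "male")), 1, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid panels are handled", {
  pairs <- data.frame(sppb_from = c(3, 5, 7), sppb_to = c(6, 6, 6),
                      age = c(70, 75, 80), sex = "female")
  m <- fit_transition_model(pairs)
  expect_true(m$degenerate)
  expect_equal(predict_transition(m, 4, 70, "female")[["6"]], 1)
  bad <- data.frame(sppb_from = c(3, 13), sppb_to = c(2, 5), age = 70,
                    sex = "female")
  expect_error(fit_transition_model(bad), "0-12")
})

test_that("build_transition_matrix composes mortality and SPPB dynamics", {
  pairs <- simulate_ordinal_pairs(1000, seed = 11)
  m <- fit_transition_model(pairs)
  # q = 1: every living row sends all mass to dead
  M1 <- build_transition_matrix(m, 75, "female", flat_life_table(1))
  expect_equal(unname(M1[1:13, 14]), rep(1, 13))
  expect_equal(sum(M1[1:13, 1:13]), 0)
  # q = 0 with identity dynamics: identity over living states
  ident <- stub_transition_model(diag(13))
  M0 <- build_transition_matrix(ident, 75, "female", flat_life_table(0))
  expect_equal(unname(M0[1:13, 1:13]), diag(13))
  # q = 0.1 with uniform dynamics: 0.1 dead, 0.9/13 per SPPB state
  unif <- stub_transition_model(matrix(1 / 13, 13, 13))
  Mu <- build_transition_matrix(unif, 75, "female", flat_life_table(0.1))
  expect_equal(unname(Mu[3, ]), c(rep(0.9 / 13, 13), 0.1))
  # stochasticity across the whole age grid
  lt <- generate_life_table()
  for (a in seq(65, 95, by = 5)) {
    M <- build_transition_matrix(m, a, "male", lt)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-9)
  }
})

test_that("run_cohort closed forms: dead start, identity transitions, zero horizon", {
  ident <- stub_transition_model(diag(13))
  lt0 <- flat_life_table(0)
  vals <- state_values(rep(1000, 13), rep(0.7, 13))
  # start entirely dead
  dead_start <- c(rep(0, 13), 1)
  tr <- run_cohort(markov_spec(75, "female", dead_start, horizon = 10,
                               discount_rate = 0), ident, vals, lt0)
  expect_equal(tr$discounted_qaly, 0)
  expect_equal(tr$discounted_cost, 0)
  # identity transitions, utility 0.7, 10 undiscounted cycles -> 7 QALYs
  alive <- c(rep(0, 5), 1, rep(0, 7))
  tr2 <- run_cohort(markov_spec(75, "female", alive, horizon = 10,
                                discount_rate = 0, discount_offset = 0),
                    ident, vals, lt0)
  expect_equal(tr2$discounted_qaly, 7.0)
  expect_equal(tr2$cost, 10000)
  # horizon 0: empty accumulators
  tr3 <- run_cohort(markov_spec(75, "female", alive, horizon = 0), ident, vals, lt0)
  expect_equal(tr3$discounted_qaly, 0)
  expect_equal(nrow(tr3$occupancy), 1)
})

test_that("cohort trace equals hand matrix powers on a two-living-state toy", {
  B <- diag(13)
  B[1, 1:2] <- c(0.7, 0.3)
  B[2, 1:2] <- c(0.2, 0.8)
  toy <- stub_transition_model(B)
  lt <- flat_life_table(0.05)
  spec <- markov_spec(70, "male", c(0.6, 0.4, rep(0, 11)), horizon = 3,
                      discount_rate = 0)
  vals <- state_values(c(500, 300, rep(0, 11)), c(0.5, 0.8, rep(0, 11)))
  tr <- run_cohort(spec, toy, vals, lt)
  # independent oracle: explicit matrix powers
  M <- build_transition_matrix(toy, 70, "male", lt)
  occ <- c(0.6, 0.4, rep(0, 11), 0)
  for (t in 1:3) {
    occ <- occ %*% M
    expect_equal(unname(tr$occupancy[t + 1, ]), as.numeric(occ), tolerance = 1e-12)
  }
  # conservation every cycle
  expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
  # dead occupancy non-decreasing
  expect_true(all(diff(tr$occupancy[, 14]) >= -1e-12))
})

test_that("fit_state_values recovers exact and noisy relationships", {
  # exact line
  d <- data.frame(sppb = rep(0:12, 4), utility = 0.6,
                  annual_cost = 5000 - 200 * rep(0:12, 4))
  sv <- fit_state_values(d)
  expect_equal(sv$annual_cost, 5000 - 200 * (0:12), tolerance = 1e-9)
  expect_equal(sv$utility, rep(0.6, 13))
  # noisy slope within 2 SE
  set.seed(21)
  n <- 2000
  sppb <- sample(0:12, n, replace = TRUE)
  d2 <- data.frame(sppb = sppb,
                   utility = 0.5 + 0.03 * sppb + rnorm(n, 0, 0.08),
                   annual_cost = pmax(0, 3000 - 150 * sppb + rnorm(n, 0, 500)))
  fit <- lm(utility ~ sppb, data = d2)
  expect_lt(abs(coef(fit)[["sppb"]] - 0.03), 2 * summary(fit)$coefficients["sppb", 2])
  sv2 <- fit_state_values(d2)
  expect_true(all(diff(sv2$utility) > 0)) # monotone in SPPB
  expect_error(fit_state_values(d2[0, ]), "no data")
})

test_that("lifetime_cea: symmetry, dominance ordering and mortality neutrality", {
  pairs <- simulate_ordinal_pairs(3000, seed = 13)
  m <- fit_transition_model(pairs)
  lt <- generate_life_table()
  vals <- state_values(4000 - 150 * (0:12), pmin(1, 0.45 + 0.035 * (0:12)))
  start <- rep(1 / 13, 13)
  # identical start distributions -> lifetime deltas equal trial deltas exactly
  eq <- lifetime_cea(-103, 0.04, start, start, m, vals, lt, 77, "female")
  expect_equal(eq$delta_cost, -103)
  expect_equal(eq$delta_qaly, 0.04)
  expect_equal(eq$post_trial_delta_qaly, 0)
  # stochastically dominating start distribution -> positive post-trial QALYs
  hi <- c(rep(0, 8), rep(0.2, 5))
  lo <- c(rep(0.2, 5), rep(0, 8))
  dom <- lifetime_cea(0, 0, hi, lo, m, vals, lt, 75, "female")
  expect_gt(dom$post_trial_delta_qaly, 0)
  # mortality neutrality: identical life expectancy across arms
  expect_equal(dom$trace_intervention$life_expectancy,
               dom$trace_control$life_expectancy, tolerance = 1e-9)
  # band accounting: high + low SPPB life-years = life expectancy
  b <- dom$trace_intervention$life_years_by_band
  expect_equal(unname(b[1] + b[2]), dom$trace_intervention$life_expectancy,
               tolerance = 1e-12)
  # discounted <= undiscounted for r > 0
  expect_lte(dom$trace_intervention$discounted_qaly, dom$trace_intervention$qaly)
  expect_lte(dom$trace_intervention$discounted_cost, dom$trace_intervention$cost)
})

test_that("cohort life expectancy matches a survival product-sum oracle", {
  ident <- stub_transition_model(diag(13))
  lt <- generate_life_table()
  H <- 35
  tr <- run_cohort(markov_spec(65, "female", c(1, rep(0, 12)), horizon = H),
                   ident, state_values(rep(0, 13), rep(1, 13)), lt)
  qs <- vapply(65:(65 + H - 1), function(a) lt$qx[lt$age == a & lt$sex == "female"],
               numeric(1))
  le_oracle <- sum(cumprod(c(1, 1 - qs))[1:H]) # person-years at cycle starts
  expect_equal(tr$life_expectancy, le_oracle, tolerance = 1e-9)
})

test_that("population weighting averages deltas and validates weights", {
  r1 <- list(delta_cost = -100, delta_qaly = 0.05)
  r2 <- list(delta_cost = 100, delta_qaly = -0.05)
  expect_equal(population_weighted(list(r1), 1)$delta_cost, -100)
  agg <- population_weighted(list(r1, r2), c(0.5, 0.5))
  expect_equal(agg$delta_cost, 0)
  expect_equal(agg$delta_qaly, 0)
  # hand-computed weighted mean over a profile grid
  rs <- list(list(delta_cost = -290, delta_qaly = 0.072),
             list(delta_cost = -200, delta_qaly = 0.058),
             list(delta_cost = -350, delta_qaly = 0.080))
  w <- c(0.5, 0.3, 0.2)
  agg2 <- population_weighted(rs, w)
  expect_equal(agg2$delta_cost, sum(w * c(-290, -200, -350)))
  expect_equal(agg2$delta_qaly, sum(w * c(0.072, 0.058, 0.080)))
  expect_error(population_weighted(list(r1, r2), c(0.6, 0.6)), "sum to 1")
})

test_that("ages map to the nearest grid profile", {
  expect_equal(nearest_grid_age(77), 75)
  expect_equal(nearest_grid_age(78), 80)
  expect_equal(nearest_grid_age(65), 65)
  expect_equal(nearest_grid_age(99), 95)
})
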