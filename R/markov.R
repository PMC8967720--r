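#' Fit an ordinal SPPB transition model to control-arm panel data
#'
#' Proportional-odds ordinal regression of next-year SPPB score on current
#' SPPB score, age and sex, fitted to annual observation pairs from the
#' control arm (the intervention is assumed to act only through the state
#' distribution at model entry, never through transition dynamics).
#'
#' @param transitions data frame of annual transition pairs with columns
#'   `sppb_from`, `sppb_to` (integers 0-12), `age` (years at the start of
#'   the pair) and `sex` (`"female"`/`"male"`).
#' @return `sppb_transition_model`: wraps the `MASS::polr` fit plus the
#'   observed outcome support. Outcomes never observed in the panel get zero
#'   probability. A panel whose outcomes are all identical yields a flagged
#'   degenerate point-mass model.
#' @export
fit_transition_model <- function(transitions) {
  need <- c("sppb_from", "sppb_to", "age", "sex")
  stopifnot(all(need %in% names(transitions)))
  tr <- transitions[stats::complete.cases(transitions[need]), need]
  if (nrow(tr) < 2) stop("panel must contain at least 2 transition pairs", call. = FALSE)
  if (any(tr$sppb_from < 0 | tr$sppb_from > 12 | tr$sppb_to < 0 | tr$sppb_to > 12)) {
    stop("SPPB scores must lie in 0-12", call. = FALSE)
  }
  tr$sex <- factor(as.character(tr$sex), levels = c("female", "male"))
  lev <- sort(unique(tr$sppb_to))
  if (length(lev) == 1L) {
    return(structure(list(fit = NULL, levels = lev, degenerate = TRUE),
                     class = "sppb_transition_model"))
  }
  # drop constant covariates (e.g. single-sex panels) from the formula
  terms_rhs <- c("sppb_from",
                 if (length(unique(tr$age)) > 1) "age",
                 if (length(unique(droplevels(tr$sex))) > 1) "sex")
  fml <- stats::as.formula(paste("y ~", paste(terms_rhs, collapse = " + ")))
  tr$y <- factor(tr$sppb_to, levels = lev, ordered = TRUE)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = tr, Hess = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # quasi-separated panels (e.g. SPPB never changes) defeat the ordinal
    # likelihood; fall back to the empirical conditional distribution,
    # with persistence for states never observed as origins
    B <- matrix(0, 13, 13, dimnames = list(as.character(0:12),
                                           as.character(0:12)))
    for (s in 0:12) {
      to <- tr$sppb_to[tr$sppb_from == s]
      if (length(to)) {
        B[s + 1, ] <- as.numeric(table(factor(to, levels = 0:12)) / length(to))
      } else {
        B[s + 1, s + 1] <- 1
      }
    }
    return(structure(list(fit = NULL, levels = lev, degenerate = FALSE,
                          empirical = TRUE, block = B,
                          cache = new.env(parent = emptyenv())),
                     class = "sppb_transition_model"))
  }
  structure(list(fit = fit, levels = lev, degenerate = FALSE,
                 empirical = FALSE, terms_rhs = terms_rhs,
                 cache = new.env(parent = emptyenv())),
            class = "sppb_transition_model")
}

# internal: proportional-odds probabilities over model$levels for a vector
# of current SPPB scores, computed from the fitted coefficients directly
# (equivalent to predict(fit, type = "probs") but vectorised and fast)
ordinal_probs <- function(model, sppb_vec, age, sex) {
  cf <- model$fit$coefficients
  zeta <- model$fit$zeta
  eta <- cf[["sppb_from"]] * sppb_vec
  if ("age" %in% names(cf)) eta <- eta + cf[["age"]] * age
  if ("sexmale" %in% names(cf)) eta <- eta + cf[["sexmale"]] * (sex == "male")
  cum <- stats::plogis(outer(-eta, zeta, "+")) # P(Y <= level_k)
  cbind(cum, 1) - cbind(0, cum)
}

# internal: 13x13 conditional-on-survival SPPB transition block, cached per
# (age, sex) since the ordinal model is fixed once fitted
alive_transition_block <- function(model, age, sex) {
  key <- paste(age, sex, sep = "|")
  if (!is.null(model$cache) && !is.null(model$cache[[key]])) {
    return(model$cache[[key]])
  }
  B <- matrix(0, 13, 13, dimnames = list(as.character(0:12), as.character(0:12)))
  if (isTRUE(model$empirical)) {
    B <- model$block
  } else if (model$degenerate) {
    B[, as.character(model$levels)] <- 1
  } else {
    P <- ordinal_probs(model, 0:12, age, sex)
    B[, as.character(model$levels)] <- P
    B <- B / rowSums(B)
  }
  if (!is.null(model$cache)) model$cache[[key]] <- B
  B
}

#' Next-cycle SPPB distribution conditional on survival
#'
#' @param model an [fit_transition_model()] result.
#' @param sppb current SPPB score (0-12).
#' @param age current age in years.
#' @param sex `"female"` or `"male"`.
#' @return length-13 probability vector over SPPB 0-12 (sums to 1).
#' @export
predict_transition <- function(model, sppb, age, sex) {
  stopifnot(inherits(model, "sppb_transition_model"), sppb >= 0, sppb <= 12)
  alive_transition_block(model, age, sex)[as.character(sppb), ]
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `sex`, `qx` (annual probability of death).
#' @param path CSV path.
#' @return data frame of class `life_table`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "qx") %in% names(lt)),
            all(lt$qx >= 0 & lt$qx <= 1))
  structure(lt, class = c("life_table", "data.frame"))
}

# internal: annual death probability lookup (exact age match required)
mortality_q <- function(life_table, age, sex) {
  i <- which(life_table$age == age & life_table$sex == sex)
  if (!length(i)) {
    stop(sprintf("life table does not cover age %s (%s)", age, sex), call. = FALSE)
  }
  q <- life_table$qx[i[1]]
  if (q < 0 || q > 1) stop("death probability outside [0,1]", call. = FALSE)
  q
}

#' Assemble the 14-state annual transition matrix
#'
#' States 1-13 are SPPB scores 0-12; state 14 is death (absorbing). All-cause
#' mortality from the life table applies identically to every living state
#' (no SPPB effect on mortality); the surviving mass is distributed over next
#' SPPB scores by the ordinal model.
#'
#' @param model [fit_transition_model()] result.
#' @param age,sex profile at the start of the cycle.
#' @param life_table data frame with columns `age`, `sex`, `qx`.
#' @return 14 x 14 row-stochastic matrix.
#' @export
build_transition_matrix <- function(model, age, sex, life_table) {
  q <- mortality_q(life_table, age, sex)
  M <- matrix(0, 14, 14,
              dimnames = list(c(as.character(0:12), "dead"),
                              c(as.character(0:12), "dead")))
  M[1:13, 1:13] <- (1 - q) * alive_transition_block(model, age, sex)
  M[1:13, 14] <- q
  M[14, 14] <- 1
  M
}

#' Markov cohort specification
#'
#' @param start_age age in years at model entry (24 months after
#'   randomisation). Ages off the 65-95-by-5 grid are mapped to the nearest
#'   grid profile by [nearest_grid_age()] before choosing start
#'   distributions, but the cohort itself ages annually from `start_age`.
#' @param sex `"female"` or `"male"`.
#' @param start_distribution probability vector over the 13 SPPB states
#'   (optionally 14 including initial dead mass); must sum to 1 within 1e-9.
#' @param discount_rate annual rate (default 0.035).
#' @param horizon cycles to run; default runs to age 100.
#' @param discount_offset years between randomisation and model entry
#'   (default 2): cycle 0 is discounted by `(1+r)^-2` so the trial-phase and
#'   model-phase streams share one time axis.
#' @param half_cycle apply a half-cycle correction (average of start- and
#'   end-of-cycle occupancy); off by default.
#' @return `markov_spec` object.
#' @export
markov_spec <- function(start_age, sex, start_distribution,
                        discount_rate = 0.035, horizon = NULL,
                        discount_offset = 2, half_cycle = FALSE) {
  sex <- match.arg(sex, c("female", "male"))
  sd_ <- as.numeric(start_distribution)
  if (length(sd_) == 13L) sd_ <- c(sd_, 0)
  if (length(sd_) != 14L) {
    stop("start_distribution must have 13 (SPPB) or 14 (+dead) entries", call. = FALSE)
  }
  if (abs(sum(sd_) - 1) > 1e-9 || any(sd_ < 0)) {
    stop("start_distribution must be a probability vector summing to 1 (tol 1e-9)",
         call. = FALSE)
  }
  if (is.null(horizon)) horizon <- max(0L, as.integer(100 - start_age))
  stopifnot(horizon >= 0)
  structure(list(start_age = start_age, sex = sex, start_distribution = sd_,
                 discount_rate = discount_rate, horizon = as.integer(horizon),
                 discount_offset = discount_offset, half_cycle = half_cycle),
            class = "markov_spec")
}

#' Map an age to the nearest modelled age-grid profile
#'
#' @param age age in years.
#' @param grid modelled ages (default 65 to 95 by 5).
#' @return the grid age nearest to `age` (lower one on ties).
#' @export
nearest_grid_age <- function(age, grid = seq(65, 95, by = 5)) {
  grid[which.min(abs(grid - age))]
}

#' Annual cost and utility per SPPB state
#'
#' @param annual_cost length-13 vector, cost of living a year in SPPB state
#'   0-12 (GBP).
#' @param utility length-13 vector of health-state utilities (`<= 1`).
#' @return `state_values` object.
#' @export
state_values <- function(annual_cost, utility) {
  stopifnot(length(annual_cost) == 13L, length(utility) == 13L,
            all(utility <= 1 + 1e-9), all(annual_cost >= 0))
  structure(list(annual_cost = as.numeric(annual_cost),
                 utility = as.numeric(utility)),
            class = "state_values")
}

#' Estimate state costs and utilities from control-arm data
#'
#' Linear regressions of annual cost and of utility on SPPB, evaluated at
#' every state 0-12 (model-based smoothing covers states sparse in the
#' data). Predicted utilities are capped at 1 and predicted costs floored at
#' 0.
#'
#' @param data data frame with columns `sppb`, `annual_cost`, `utility`.
#' @return a [state_values()] object.
#' @export
fit_state_values <- function(data) {
  stopifnot(all(c("sppb", "annual_cost", "utility") %in% names(data)))
  data <- data[stats::complete.cases(data[c("sppb", "annual_cost", "utility")]), ]
  if (!nrow(data)) stop("no data to fit state values", call. = FALSE)
  nd <- data.frame(sppb = 0:12)
  fc <- stats::lm(annual_cost ~ sppb, data = data)
  fu <- stats::lm(utility ~ sppb, data = data)
  state_values(pmax(0, stats::predict(fc, nd)),
               pmin(1, stats::predict(fu, nd)))
}

#' Run the Markov cohort simulation
#'
#' Propagates the start distribution through age-specific transition
#' matrices, accumulating discounted costs and QALYs. With the default (no
#' half-cycle correction), each cycle's cost and utility accrue to the
#' occupancy at the start of the cycle, discounted by
#' `(1+r)^-(cycle + discount_offset)`.
#'
#' @param spec a [markov_spec()].
#' @param model a [fit_transition_model()] result.
#' @param values a [state_values()].
#' @param life_table data frame with `age`, `sex`, `qx`.
#' @return `cohort_trace`: list with `occupancy`
#'   ((horizon+1) x 14 matrix), `discounted_cost`, `discounted_qaly`,
#'   undiscounted `cost`/`qaly`, `life_expectancy` and `life_years_by_band`
#'   (years in SPPB 8-12 vs 0-7).
#' @export
run_cohort <- function(spec, model, values, life_table) {
  stopifnot(inherits(spec, "markov_spec"), inherits(values, "state_values"))
  H <- spec$horizon
  occ <- matrix(0, H + 1, 14,
                dimnames = list(NULL, c(as.character(0:12), "dead")))
  occ[1, ] <- spec$start_distribution
  disc_cost <- disc_qaly <- raw_cost <- raw_qaly <- 0
  ly_high <- ly_low <- 0 # SPPB 8-12 vs 0-7
  r <- spec$discount_rate
  if (H > 0) {
    for (t in 0:(H - 1)) {
      M <- build_transition_matrix(model, spec$start_age + t, spec$sex, life_table)
      occ[t + 2, ] <- occ[t + 1, ] %*% M
      w <- if (spec$half_cycle) (occ[t + 1, 1:13] + occ[t + 2, 1:13]) / 2
           else occ[t + 1, 1:13]
      cyc_cost <- sum(w * values$annual_cost)
      cyc_qaly <- sum(w * values$utility)
      df <- (1 + r)^(-(t + spec$discount_offset))
      disc_cost <- disc_cost + cyc_cost * df
      disc_qaly <- disc_qaly + cyc_qaly * df
      raw_cost <- raw_cost + cyc_cost
      raw_qaly <- raw_qaly + cyc_qaly
      ly_high <- ly_high + sum(w[9:13]) # SPPB 8-12
      ly_low <- ly_low + sum(w[1:8])    # SPPB 0-7
    }
  }
  structure(list(occupancy = occ,
                 discounted_cost = disc_cost, discounted_qaly = disc_qaly,
                 cost = raw_cost, qaly = raw_qaly,
                 life_expectancy = ly_high + ly_low,
                 life_years_by_band = c(sppb_8_12 = ly_high, sppb_0_7 = ly_low),
                 spec = spec),
            class = "cohort_trace")
}

#' Lifetime cost-effectiveness: trial phase plus Markov extrapolation
#'
#' Runs one cohort per arm — identical in every respect except the SPPB
#' distribution at model entry — and adds the discounted post-24-month
#' differences to the within-trial increments.
#'
#' @param trial_delta_cost,trial_delta_qaly within-trial (months 0-24)
#'   increments, intervention minus control.
#' @param start_int,start_ctrl per-arm SPPB distributions at 24 months.
#' @param model,values,life_table as in [run_cohort()].
#' @param start_age,sex profile; age is mapped to the model grid via
#'   [nearest_grid_age()].
#' @param ... passed to [markov_spec()] (e.g. `discount_rate`, `horizon`,
#'   `half_cycle`).
#' @param granularity ICER reporting granularity (GBP).
#' @return `lifetime_cea` object: lifetime and model-phase increments,
#'   per-arm traces, and the ICER/dominance classification.
#' @export
lifetime_cea <- function(trial_delta_cost, trial_delta_qaly,
                         start_int, start_ctrl, model, values, life_table,
                         start_age, sex, ..., granularity = 50) {
  age0 <- nearest_grid_age(start_age)
  spec_i <- markov_spec(age0, sex, start_int, ...)
  spec_c <- markov_spec(age0, sex, start_ctrl, ...)
  tr_i <- run_cohort(spec_i, model, values, life_table)
  tr_c <- run_cohort(spec_c, model, values, life_table)
  post_dc <- tr_i$discounted_cost - tr_c$discounted_cost
  post_dq <- tr_i$discounted_qaly - tr_c$discounted_qaly
  dc <- trial_delta_cost + post_dc
  dq <- trial_delta_qaly + post_dq
  structure(list(delta_cost = dc, delta_qaly = dq,
                 post_trial_delta_cost = post_dc,
                 post_trial_delta_qaly = post_dq,
                 trial_delta_cost = trial_delta_cost,
                 trial_delta_qaly = trial_delta_qaly,
                 classification = classify_icer(dc, dq, granularity = granularity),
                 trace_intervention = tr_i, trace_control = tr_c),
            class = "lifetime_cea")
}

#' Population-weighted aggregate of per-profile results
#'
#' @param results list of [lifetime_cea()] results (or any lists with
#'   `delta_cost` and `delta_qaly`).
#' @param weights non-negative weights summing to 1 (e.g. the population
#'   age/sex composition).
#' @param granularity ICER reporting granularity.
#' @return list with weighted `delta_cost`, `delta_qaly` and a
#'   classification.
#' @export
population_weighted <- function(results, weights, granularity = 50) {
  stopifnot(length(results) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  dc <- sum(weights * vapply(results, function(x) x$delta_cost, numeric(1)))
  dq <- sum(weights * vapply(results, function(x) x$delta_qaly, numeric(1)))
  list(delta_cost = dc, delta_qaly = dq,
       classification = classify_icer(dc, dq, granularity = granularity))
}
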