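#' Configuration of the synthetic trial generator
#'
#' Defaults encode the emulated trial's headline characteristics: 777
#' participants allocated 1:1 across three sites, 66% female, mean age 77
#' (SD 6, truncated at 65), baseline SPPB 4-9 (the eligibility window), an
#' adjusted 24-month SPPB difference of 0.49, true incremental QALYs of
#' 0.040 and incremental total cost of -GBP 103 over 24 months, and 58%
#' complete cases with missingness depending on arm, session attendance and
#' baseline utility (MAR by construction).
#'
#' @param n participants (default 777).
#' @param prop_female proportion female (default 0.66).
#' @param age_mean,age_sd,age_min age distribution (normal truncated below).
#' @param n_sites number of recruiting sites.
#' @param sppb_effect_24m target arm difference in SPPB at 24 months.
#' @param incremental_qaly true discounted incremental QALYs over 24 months.
#' @param incremental_cost true discounted incremental total cost (GBP),
#'   including the intervention delivery cost.
#' @param intervention_cost per-participant delivery cost (GBP).
#' @param complete_case_fraction target fraction of complete cases in (0,1].
#' @param discount_rate annual rate used to define the discounted truths.
#' @param baseline_cost_imbalance multiplier applied to the intervention
#'   arm's baseline-period resource-use means (1 = balanced, default).
#' @param seed RNG seed.
#' @return `synth_config` list.
#' @export
synth_config <- function(n = 777, prop_female = 0.66, age_mean = 77,
                         age_sd = 6, age_min = 65, n_sites = 3,
                         sppb_effect_24m = 0.49, incremental_qaly = 0.040,
                         incremental_cost = -103, intervention_cost = 622,
                         complete_case_fraction = 0.58, discount_rate = 0.035,
                         baseline_cost_imbalance = 1, seed = 1) {
  cfg <- list(n = as.integer(n), prop_female = prop_female,
              age_mean = age_mean, age_sd = age_sd, age_min = age_min,
              n_sites = as.integer(n_sites),
              sppb_effect_24m = sppb_effect_24m,
              incremental_qaly = incremental_qaly,
              incremental_cost = incremental_cost,
              intervention_cost = intervention_cost,
              complete_case_fraction = complete_case_fraction,
              discount_rate = discount_rate,
              baseline_cost_imbalance = baseline_cost_imbalance,
              seed = as.integer(seed))
  if (cfg$n < 2) stop("n must be >= 2", call. = FALSE)
  if (cfg$prop_female < 0 || cfg$prop_female > 1) {
    stop("prop_female must be in [0,1]", call. = FALSE)
  }
  if (cfg$complete_case_fraction <= 0 || cfg$complete_case_fraction > 1) {
    stop("complete_case_fraction must be in (0,1]", call. = FALSE)
  }
  # a utility lift too large for the instrument range cannot be embedded
  if (abs(cfg$incremental_qaly) > 0.5) {
    stop("incremental_qaly too large to embed in the utility range", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a toy monotone value set
#'
#' Enumerates every profile of the instrument and assigns
#' `1 - sum(w_d * (level_d - 1)/(L_d - 1))` with fixed dimension weights
#' scaled so the worst profile hits the instrument's documented floor
#' (-0.594 for the EQ-5D-3L crosswalk, -0.285 for EQ-5D-5L, 0.203 for
#' SF-6D) and full health maps to 1. Monotone non-increasing in every
#' dimension by construction. Deterministic: these are synthetic stand-ins
#' for the licensed national tariffs, not re-derivations of them.
#'
#' @param instrument instrument code (see [instrument_levels()]).
#' @return a [value_set()] covering all profiles.
#' @export
generate_value_set <- function(instrument) {
  lev <- instrument_levels(instrument)
  fl <- instrument_floor(instrument)
  props <- if (length(lev) == 5L) c(0.30, 0.15, 0.20, 0.25, 0.10)
           else c(0.25, 0.10, 0.15, 0.25, 0.15, 0.10)
  w <- props * (1 - fl)
  grid <- do.call(expand.grid, lapply(lev, seq_len))
  # convex per-level decrements (mild problems cost less than severe ones),
  # as in published tariffs; exponent > 1 keeps the grid fine near 1
  dec <- as.matrix(sweep(sweep(grid, 2, 1, "-"), 2, lev - 1L, "/")^1.35) %*% w
  keys <- apply(grid, 1, paste, collapse = "-")
  value_set(instrument, keys, 1 - as.numeric(dec), fl)
}

#' Generate a toy life table
#'
#' Gompertz hazard `h(x) = a * exp(b * x)` converted to annual death
#' probabilities `q = 1 - exp(-h)`, calibrated so a 65-year-old woman has
#' q of about 1%, with a 45% higher hazard for men. Ages 60-105, strictly
#' increasing in age, female below male at every age, all probabilities in
#' (0,1). Deterministic synthetic stand-in for a national life table.
#'
#' @param ages integer vector of ages (default 60:105).
#' @return data frame (`age`, `sex`, `qx`) of class `life_table`.
#' @export
generate_life_table <- function(ages = 60:105) {
  b <- 0.095
  a <- 0.01 / exp(b * 65)
  hf <- a * exp(b * ages)
  hm <- hf * 1.45
  lt <- rbind(data.frame(age = ages, sex = "female", qx = 1 - exp(-hf)),
              data.frame(age = ages, sex = "male", qx = 1 - exp(-hm)))
  lt$qx <- pmin(lt$qx, 0.999)
  structure(lt, class = c("life_table", "data.frame"))
}

#' Default NHS/PSS unit costs (synthetic fixture, 2018-19 GBP)
#'
#' Stylised unit costs of the kind taken from national costing sources; the
#' values are plausible but synthetic stand-ins.
#'
#' @return a [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  unit_cost_table(
    items = c("gp_consultation", "nurse_consultation", "outpatient_attendance",
              "a_and_e_attendance", "inpatient_day", "social_care_contact"),
    unit_costs = c(39, 11, 135, 160, 345, 27),
    price_year = "2018-19",
    source = "synthetic stand-in"
  )
}

# internal: discounted AUC weight carried by a constant post-baseline
# utility lift (months 6, 12 and 24), used to size the per-timepoint effect
qaly_lift_weight <- function(r) 0.75 + 1 / (1 + r)

# internal: snap latent utilities to the nearest utility achievable under
# the value set; returns the corresponding profile keys and snapped values
snap_to_value_set <- function(latent, vs) {
  us <- sort(unique(vs$map))
  rep_profile <- names(vs$map)[match(us, vs$map)]
  x <- pmin(pmax(latent, vs$floor), 1)
  lo <- findInterval(x, us, all.inside = TRUE)
  hi <- pmin(lo + 1L, length(us))
  pick <- ifelse(abs(us[hi] - x) < abs(x - us[lo]), hi, lo)
  list(profile = rep_profile[pick], utility = us[pick])
}

#' Generate a synthetic trial with known ground truth
#'
#' Simulates participant covariates, longitudinal SPPB (baseline restricted
#' to the 4-9 eligibility window, 0-12 thereafter), EQ-5D-5L profiles whose
#' crosswalk-tariff utilities embed the configured QALY effect (latent
#' utilities are snapped to the nearest value-set profile so generation and
#' lookup agree), SF-6D utilities, negative-binomial resource-use counts
#' with SPPB-dependent means embedding the cost effect, and monotone MAR
#' missingness calibrated to the target complete-case fraction (the number
#' of complete cases is hit exactly; incompleteness probability rises with
#' control allocation, low attendance and low baseline utility).
#'
#' @param config a [synth_config()].
#' @return `synthetic_trial` list: `participants` (one row each; EQ-5D
#'   profile strings per timepoint, SF-6D utilities, SPPB, covariates,
#'   missingness encoded as `NA`), `resource_use` (long: id, period, item,
#'   count), `value_set` (the crosswalk tariff used), `truth` (configured
#'   and realised incremental quantities plus the pre-missingness
#'   per-participant QALYs and costs), and `config`.
#' @export
generate_trial <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n
  r <- config$discount_rate
  vs <- generate_value_set("EQ5D5L_crosswalk")
  prices <- default_unit_costs()

  arm <- sample(c(rep("intervention", ceiling(n / 2)),
                  rep("control", n - ceiling(n / 2))))
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age < config$age_min)) {
    i <- age < config$age_min
    age[i] <- stats::rnorm(sum(i), config$age_mean, config$age_sd)
  }
  age <- round(age)
  site <- sample(paste0("site", seq_len(config$n_sites)), n, replace = TRUE)
  is_int <- arm == "intervention"
  attendance <- ifelse(is_int, stats::rbeta(n, 3.2, 1.8), 0)

  # SPPB: eligibility window 4-9 at baseline; gentle decline; intervention
  # effect ramps to the configured 24-month difference
  sppb0 <- sample(4:9, n, replace = TRUE,
                  prob = c(0.08, 0.15, 0.22, 0.25, 0.20, 0.10))
  drift <- c(-0.15, -0.30, -0.60)
  eff <- c(0.40, 0.55, config$sppb_effect_24m)
  sppb_post <- sapply(1:3, function(k) {
    lat <- sppb0 + drift[k] + eff[k] * is_int + stats::rnorm(n, 0, 1.2)
    pmin(pmax(round(lat), 0L), 12L)
  })
  sppb6 <- sppb_post[, 1]; sppb12 <- sppb_post[, 2]; sppb24 <- sppb_post[, 3]

  # utilities: latent scale, then snapped to the crosswalk value set
  du <- config$incremental_qaly / qaly_lift_weight(r)
  u0_lat <- 0.50 + 0.035 * sppb0 + stats::rnorm(n, 0, 0.10)
  decline <- c(-0.005, -0.010, -0.020)
  u_lat <- sapply(1:3, function(k) {
    u0_lat + decline[k] + du * is_int + stats::rnorm(n, 0, 0.07)
  })
  s0 <- snap_to_value_set(u0_lat, vs)
  s6 <- snap_to_value_set(u_lat[, 1], vs)
  s12 <- snap_to_value_set(u_lat[, 2], vs)
  s24 <- snap_to_value_set(u_lat[, 3], vs)

  sf_floor <- instrument_floor("SF6D")
  sf <- function(lat) pmin(pmax(0.45 + 0.55 * lat, sf_floor), 1)
  sf6d <- cbind(sf(u0_lat), sf(u_lat[, 1]), sf(u_lat[, 2]), sf(u_lat[, 3]))

  # resource use: NB counts, means falling with SPPB; a direct arm
  # multiplier sized so the discounted resource-cost difference plus the
  # intervention cost delivers the configured incremental total cost
  items <- names(prices$costs)
  base_mu <- c(gp_consultation = 1.5, nurse_consultation = 1.0,
               outpatient_attendance = 1.2, a_and_e_attendance = 0.25,
               inpatient_day = 1.8, social_care_contact = 2.0)
  sppb_mid <- cbind(base = sppb0, p1 = (sppb0 + sppb6) / 2,
                    p2 = (sppb6 + sppb12) / 2, p4 = sppb24)
  # expected discounted 24-month resource cost per participant at unit arm
  # multiplier (gap period = mean of its neighbours, year 2 discounted)
  ec <- sapply(2:4, function(p) {
    exp(0.08 * (6.5 - sppb_mid[, p])) * sum(base_mu[items] * prices$costs[items])
  })
  edisc <- ec[, 1] + ec[, 2] + ((ec[, 2] + ec[, 3]) / 2 + ec[, 3]) / (1 + r)
  needed <- config$incremental_cost - config$intervention_cost
  arm_mult <- (mean(edisc[!is_int]) + needed) / mean(edisc[is_int])
  if (arm_mult <= 0) {
    stop("configured incremental_cost is too negative to embed in resource use",
         call. = FALSE)
  }
  periods <- c("baseline", "0-6", "6-12", "18-24")
  ru <- vector("list", length(periods))
  counts_mat <- array(0L, dim = c(n, length(periods), length(items)),
                      dimnames = list(NULL, periods, items))
  for (p in seq_along(periods)) {
    sev <- exp(0.08 * (6.5 - sppb_mid[, p]))
    mult <- rep(1, n)
    if (periods[p] != "baseline") mult[is_int] <- arm_mult
    else mult[is_int] <- config$baseline_cost_imbalance
    for (j in seq_along(items)) {
      mu <- base_mu[items[j]] * sev * mult
      counts_mat[, p, j] <- stats::rnbinom(n, size = 1.0, mu = mu)
    }
  }

  # ground truth from the complete (pre-missingness) data
  pc <- sapply(periods, function(p) {
    counts_mat[, p, ] %*% prices$costs[items]
  })
  gap <- impute_gap_period(pc[, "6-12"], pc[, "18-24"])
  total_cost_true <- total_24m_cost(pc[, "0-6"], pc[, "6-12"], gap,
                                    pc[, "18-24"],
                                    intervention_cost = config$intervention_cost * is_int,
                                    discount_rate = r)
  qaly_true <- qaly_auc(s0$utility, s6$utility, s12$utility, s24$utility,
                        discount_rate = r)

  # MAR monotone missingness: exactly round(f*n) complete cases, selected
  # by a logistic score of arm, attendance and baseline utility
  n_cc <- round(config$complete_case_fraction * n)
  p_complete <- stats::plogis(0.4 - 0.5 * !is_int + 1.5 * attendance +
                                1.0 * (u0_lat - 0.75))
  incomplete <- if (n_cc < n) {
    sample(seq_len(n), n - n_cc, prob = pmax(1e-6, 1 - p_complete))
  } else integer(0)
  dropout <- rep(NA_integer_, n) # first missing assessment: 1=6m, 2=12m, 3=24m
  dropout[incomplete] <- sample(1:3, length(incomplete), replace = TRUE,
                                prob = c(0.45, 0.30, 0.25))

  participants <- data.frame(
    id = seq_len(n), arm = arm, age = age, sex = sex, site = site,
    attendance = attendance,
    sppb_0m = sppb0, sppb_6m = sppb6, sppb_12m = sppb12, sppb_24m = sppb24,
    eq5d_0m = s0$profile, eq5d_6m = s6$profile, eq5d_12m = s12$profile,
    eq5d_24m = s24$profile,
    sf6d_0m = sf6d[, 1], sf6d_6m = sf6d[, 2], sf6d_12m = sf6d[, 3],
    sf6d_24m = sf6d[, 4],
    stringsAsFactors = FALSE
  )
  # booklet k missing knocks out that assessment and all later ones
  miss_cols <- list(c("eq5d_6m", "sf6d_6m", "sppb_6m"),
                    c("eq5d_12m", "sf6d_12m", "sppb_12m"),
                    c("eq5d_24m", "sf6d_24m", "sppb_24m"))
  miss_period <- c("0-6", "6-12", "18-24")
  for (k in 1:3) {
    hit <- which(!is.na(dropout) & dropout <= k)
    for (cl in miss_cols[[k]]) participants[hit, cl] <- NA
    counts_mat[hit, miss_period[k], ] <- NA
  }

  resource_use <- data.frame(
    id = rep(seq_len(n), times = length(periods) * length(items)),
    period = rep(rep(periods, each = n), times = length(items)),
    item = rep(items, each = n * length(periods)),
    count = as.vector(counts_mat),
    stringsAsFactors = FALSE
  )

  truth <- list(
    configured = list(incremental_qaly = config$incremental_qaly,
                      incremental_cost = config$incremental_cost,
                      sppb_effect_24m = config$sppb_effect_24m),
    realized = list(
      incremental_qaly = mean(qaly_true[is_int]) - mean(qaly_true[!is_int]),
      incremental_cost = mean(total_cost_true[is_int]) -
        mean(total_cost_true[!is_int]),
      sppb_diff_24m = mean(sppb24[is_int]) - mean(sppb24[!is_int]),
      complete_case_fraction = 1 - length(incomplete) / n
    ),
    per_participant = data.frame(id = seq_len(n), arm = arm,
                                 qaly = qaly_true,
                                 total_cost = total_cost_true),
    intervention_cost = config$intervention_cost,
    seed = config$seed
  )
  structure(list(participants = participants, resource_use = resource_use,
                 value_set = vs, truth = truth, config = config),
            class = "synthetic_trial")
}

#' Write a synthetic trial to plain-text files
#'
#' Writes `participants.csv`, `resource_use.csv`, `lifetable.csv`,
#' `valueset_crosswalk.csv` and `truth.json` under `dir`.
#'
#' @param trial a [generate_trial()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$resource_use, file.path(dir, "resource_use.csv"),
                   row.names = FALSE)
  utils::write.csv(generate_life_table(), file.path(dir, "lifetable.csv"),
                   row.names = FALSE)
  vs <- trial$value_set
  utils::write.csv(data.frame(instrument = vs$instrument,
                              profile = names(vs$map),
                              utility = unname(vs$map), floor = vs$floor),
                   file.path(dir, "valueset_crosswalk.csv"), row.names = FALSE)
  tr <- trial$truth
  tr$per_participant <- NULL # large; reproducible from the seed
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
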