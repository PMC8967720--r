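# Shared fixtures, all built in code.

# Table-style costing specification shipped with the package
costing_fixture_path <- function() {
  system.file("extdata", "programme_costing.csv", package = "sppbcea")
}

# a small fully enumerated toy value set on a 2-dimension, 3-level system
# is impossible under the supported instruments, so tests use the real
# generated sets; this helper gives the crosswalk set without re-deriving it
# in every test
crosswalk_vs <- local({
  vs <- NULL
  function() {
    if (is.null(vs)) vs <<- generate_value_set("EQ5D5L_crosswalk")
    vs
  }
})

# stub transition model whose conditional-on-survival block is set directly,
# bypassing the fitted ordinal model (a deliberate test seam: the cache is
# consulted before the model coefficients)
stub_transition_model <- function(block, ages = 60:105,
                                  sexes = c("female", "male")) {
  stopifnot(all(dim(block) == c(13, 13)),
            max(abs(rowSums(block) - 1)) < 1e-12)
  cache <- new.env(parent = emptyenv())
  for (a in ages) for (s in sexes) cache[[paste(a, s, sep = "|")]] <- block
  structure(list(fit = NULL, levels = 0:12, degenerate = FALSE, cache = cache),
            class = "sppb_transition_model")
}

# constant-mortality life table (same q at every age/sex)
flat_life_table <- function(q, ages = 60:105) {
  structure(rbind(data.frame(age = ages, sex = "female", qx = q),
                  data.frame(age = ages, sex = "male", qx = q)),
            class = c("life_table", "data.frame"))
}

# simulate annual SPPB transition pairs from a known proportional-odds model:
# logit P(Y <= k) = zeta_k - (b_sppb*sppb + b_age*age + b_sex*male)
simulate_ordinal_pairs <- function(n, b_sppb = 0.9, b_age = -0.03,
                                   b_sex = -0.4, seed = 1) {
  set.seed(seed)
  sppb_from <- sample(0:12, n, replace = TRUE)
  age <- sample(65:95, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  eta <- b_sppb * sppb_from + b_age * age + b_sex * (sex == "male")
  zeta <- b_sppb * seq(0.5, 11.5, by = 1) + b_age * 80 # 12 thresholds
  lat <- eta + stats::rlogis(n)
  sppb_to <- findInterval(lat, zeta) # 0..12
  data.frame(sppb_from = sppb_from, sppb_to = sppb_to, age = age, sex = sex)
}
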