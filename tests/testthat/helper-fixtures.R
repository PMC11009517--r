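# Small in-code fixtures shared across test files

# A 3-parameter toy registry with one pro-inflammatory, one
# anti-inflammatory and one near-neutral parameter, none energy-adjusted so
# intakes can be fed in directly.
toy_registry <- function() {
  tibble::tibble(
    name = c("sfa", "fibre", "iron"),
    unit = c("g", "g", "mg"),
    global_mean = c(25, 18, 12),
    global_sd = c(8, 5, 4),
    effect_score = c(0.37, -0.66, 0.03),
    energy_adjust = c(FALSE, FALSE, FALSE)
  )
}

# Random registry of k parameters (not energy-adjusted)
random_registry <- function(k) {
  tibble::tibble(
    name = paste0("p", seq_len(k)),
    unit = "g",
    global_mean = stats::runif(k, 5, 100),
    global_sd = stats::runif(k, 1, 20),
    effect_score = stats::runif(k, -0.7, 0.7),
    energy_adjust = FALSE
  )
}

# Straight-line reimplementation of the four DII scoring steps, kept
# deliberately independent of the package internals: explicit loops, no
# shared helpers.
dii_by_hand <- function(intakes, registry) {
  totals <- numeric(nrow(intakes))
  for (i in seq_len(nrow(intakes))) {
    total <- 0
    for (j in seq_len(nrow(registry))) {
      x <- intakes[[registry$name[j]]][i]
      z <- (x - registry$global_mean[j]) / registry$global_sd[j]
      prop <- stats::pnorm(z)
      centered <- 2 * prop - 1
      total <- total + centered * registry$effect_score[j]
    }
    totals[i] <- total
  }
  totals
}

# Minimal valid cohort table (wide, one row per participant) for the
# exclusion cascade, with all participants eligible by default.
eligible_cohort <- function(n) {
  tibble::tibble(
    participant_id = seq_len(n),
    age = rep(35, n),
    anti_obesity_meds = 0L,
    pregnant = 0L, lactating = 0L,
    energy = rep(2200, n),
    a260_a280 = rep(1.85, n),
    weight_baseline = 70, height_baseline = 1.7,
    wc_baseline = 90, hc_baseline = 100,
    weight_followup = 71, wc_followup = 91, hc_followup = 100
  )
}

# Analysis-shaped frame for model tests: quartile factor, binary stratum,
# binary outcome drawn from a configurable 8-cell logistic model.
model_frame <- function(n, cell_logor = matrix(0, 4, 2),
                        stratum_logor = 0, intercept = 0) {
  q <- sample(1:4, n, replace = TRUE)
  s <- stats::rbinom(n, 1, 0.5)
  lp <- intercept + stratum_logor * s + cell_logor[cbind(q, s + 1)]
  tibble::tibble(
    y = stats::rbinom(n, 1, stats::plogis(lp)),
    dii_quartile = factor(paste0("Q", q), levels = paste0("Q", 1:4)),
    stratum = s
  )
}
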