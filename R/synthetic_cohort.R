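#' Configuration for the synthetic cohort generator
#'
#' Bundles every generative parameter: cohort size, seed, SNP specs and
#' minor-allele frequencies, the intake model (log-normal intakes scaling
#' with energy, tied together by a latent "inflammatory diet" factor), the
#' covariate model, baseline anthropometry distributions with their
#' DII-dependence slopes, and the outcome effect model.
#'
#' The effect model is expressed on the scale the analysis estimates:
#' per-outcome intercept, a stratum main effect (log-OR of the stratum-1 Q1
#' cell vs the stratum-0 Q1 cell), and a 4 x 2 matrix of within-stratum
#' quartile log-ORs (rows Q1..Q4, columns stratum 0/1; row Q1 must be zero).
#' So \code{cell_logor$wc[2, 1] = log(1.4)} makes the generative odds ratio of
#' the (Q2, stratum 0) cell against its own stratum's Q1 cell equal 1.4 for
#' the WC-increase outcome.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param snp_specs SNP table (see [default_snp_specs()]); \code{maf} is the
#'   risk-allele (minor-allele) frequency used for simulation.
#' @param registry DII parameter registry the intakes are generated around.
#' @param stratifier Which stratum carries the outcome effects: one of the
#'   SNP ids (dominant model), "grs" (median split of the OR-weighted score),
#'   or "none".
#' @param stratum_logor Stratum main effect (log-OR), shared by wc/whr/vai
#'   outcomes.
#' @param intercepts Named per-outcome logistic intercepts (bmi, wc, whr,
#'   vai).
#' @param cell_logor Named list of 4 x 2 within-stratum quartile log-OR
#'   matrices per outcome (defaults: all zero).
#' @param grs_per_allele_logor Per-allele log-OR of each SNP on the
#'   BMI-increase outcome, the generative truth behind the GRS weights.
#' @param covariate_logor Named coefficients of the covariate effects on
#'   every outcome logit (age per year, male, energy per kcal, education_high,
#'   pa moderate/high, smoking ex/current); covariates are centered at
#'   typical values internally so the intercept stays interpretable.
#' @param intake_correlation Loading of the latent inflammatory-diet factor
#'   on each parameter (signed by the parameter's effect score); 0 gives
#'   independent intakes.
#' @param intake_noise Log-scale SD of the parameter-specific intake noise.
#' @param energy_meanlog,energy_sdlog Log-normal energy intake parameters
#'   (kcal/day).
#' @param energy_latent_slope Log-scale effect of the latent factor on
#'   energy (negative: pro-inflammatory diets are lower-energy after
#'   adjustment, as seen in quartile descriptives).
#' @param delta_scales Half-normal scale of each measure's change magnitude
#'   (BMI kg/m^2, WC cm, WHR, VAI).
#' @param baseline_dii_slopes Additive effect of a 1-SD higher DII on
#'   baseline BMI, WC and WHR (negative defaults mirror the inverse
#'   cross-sectional association).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n = 4480, seed = 1,
                       snp_specs = default_snp_specs(),
                       registry = default_dii_registry(),
                       stratifier = "none",
                       stratum_logor = 0.1,
                       intercepts = c(bmi = 0, wc = 0, whr = 0, vai = 0),
                       cell_logor = list(),
                       grs_per_allele_logor = c(rs1121980 = 0.10,
                                                rs1421085 = 0.12,
                                                rs8050136 = 0.11),
                       covariate_logor = c(age = 0.01, male = 0.20,
                                           energy = 2e-4,
                                           education_high = 0.10,
                                           pa_moderate = -0.05,
                                           pa_high = -0.10,
                                           smoking_ex = 0.05,
                                           smoking_current = 0.15),
                       intake_correlation = 0.25,
                       intake_noise = 0.30,
                       energy_meanlog = log(2300),
                       energy_sdlog = 0.25,
                       energy_latent_slope = -0.10,
                       delta_scales = c(bmi = 1.6, wc = 5.0,
                                        whr = 0.035, vai = 0.12),
                       baseline_dii_slopes = c(bmi = -0.45, wc = -1.2,
                                               whr = -0.007)) {
  stopifnot(n > 0, intake_noise > 0, energy_sdlog > 0,
            all(delta_scales > 0),
            all(snp_specs$maf > 0), all(snp_specs$maf <= 0.5))
  outcomes <- c("bmi", "wc", "whr", "vai")
  stopifnot(all(outcomes %in% names(intercepts)))
  stopifnot(stratifier %in% c(snp_specs$snp_id, "grs", "none"))
  for (o in outcomes) {
    if (is.null(cell_logor[[o]])) {
      cell_logor[[o]] <- matrix(0, 4, 2)
    }
    m <- cell_logor[[o]]
    if (!is.matrix(m) || !all(dim(m) == c(4, 2)) || any(!is.finite(m))) {
      stop("cell_logor$", o, " must be a finite 4 x 2 matrix", call. = FALSE)
    }
    if (any(m[1, ] != 0)) {
      stop("cell_logor$", o, " row Q1 must be zero (within-stratum reference)",
           call. = FALSE)
    }
  }
  if (stratifier == "grs" && any(cell_logor$bmi != 0)) {
    stop("With stratifier = 'grs' the BMI outcome defines the GRS weights ",
         "and cannot carry stratified cell effects", call. = FALSE)
  }
  structure(list(
    n = n, seed = seed, snp_specs = snp_specs, registry = registry,
    stratifier = stratifier, stratum_logor = stratum_logor,
    intercepts = intercepts, cell_logor = cell_logor,
    grs_per_allele_logor = grs_per_allele_logor,
    covariate_logor = covariate_logor,
    intake_correlation = intake_correlation, intake_noise = intake_noise,
    energy_meanlog = energy_meanlog, energy_sdlog = energy_sdlog,
    energy_latent_slope = energy_latent_slope,
    delta_scales = delta_scales,
    baseline_dii_slopes = baseline_dii_slopes
  ), class = "sim_config")
}

#' Within-stratum quartile log-OR matrix from target odds ratios
#'
#' @param or_s0,or_s1 Length-4 vectors of within-stratum odds ratios for
#'   Q1..Q4 against Q1 (first element must be 1).
#' @return A 4 x 2 log-OR matrix for [sim_config()]'s \code{cell_logor}.
#' @export
cell_logor_from_or <- function(or_s0, or_s1 = c(1, 1, 1, 1)) {
  stopifnot(length(or_s0) == 4, length(or_s1) == 4,
            or_s0[1] == 1, or_s1[1] == 1,
            all(or_s0 > 0), all(or_s1 > 0))
  cbind(log(or_s0), log(or_s1))
}

#' Simulate genotypes in Hardy-Weinberg equilibrium
#'
#' Independent SNPs; each participant's risk-allele count is Binomial(2, q)
#' at risk-allele frequency q, i.e. genotype probabilities
#' ((1-q)^2, 2q(1-q), q^2).
#'
#' @param n Number of participants.
#' @param snp_specs SNP table with \code{maf} as risk-allele frequency.
#' @param ids Participant ids.
#' @return List with \code{counts} (integer risk-allele counts) and
#'   \code{calls} (two-letter allele-pair strings) tibbles.
#' @export
simulate_genotypes <- function(n, snp_specs = default_snp_specs(),
                               ids = seq_len(n)) {
  counts <- tibble::tibble(participant_id = ids)
  calls <- tibble::tibble(participant_id = ids)
  for (i in seq_len(nrow(snp_specs))) {
    g <- stats::rbinom(n, 2, snp_specs$maf[i])
    counts[[snp_specs$snp_id[i]]] <- as.integer(g)
    risk <- snp_specs$risk_allele[i]
    other <- setdiff(c(snp_specs$major_allele[i], snp_specs$minor_allele[i]),
                     risk)
    calls[[snp_specs$snp_id[i]]] <- c(
      paste0(other, other), paste0(other, risk), paste0(risk, risk))[g + 1]
  }
  list(counts = counts, calls = calls)
}

# Truncated log-normal energy draw tied to the latent diet factor
simulate_energy <- function(n, config, latent) {
  lo <- stats::plnorm(810, config$energy_meanlog, config$energy_sdlog)
  hi <- stats::plnorm(4190, config$energy_meanlog, config$energy_sdlog)
  base <- stats::qlnorm(stats::runif(n, lo, hi),
                        config$energy_meanlog, config$energy_sdlog)
  pmin(pmax(base * exp(config$energy_latent_slope * latent), 810), 4190)
}

#' Simulate nutrient-intake profiles
#'
#' Energy is truncated log-normal; every other registry parameter is a
#' log-normal multiple of its registry global mean on the per-1000-kcal
#' scale, scaled back up by the participant's energy. A shared latent factor
#' loads on each parameter with the sign of its inflammatory effect score, so
#' pro-inflammatory parameters rise together while anti-inflammatory ones
#' fall — reproducing the fibre-down/SFA-up gradient across DII quartiles.
#'
#' @param n Number of participants.
#' @param config A [sim_config()].
#' @param latent Optional latent factor vector (standard normal by default).
#' @param ids Participant ids.
#' @return List with \code{intakes} (participant_id, energy, one column per
#'   registry parameter; daily amounts) and \code{latent}.
#' @export
simulate_intakes <- function(n, config, latent = NULL, ids = seq_len(n)) {
  if (is.null(latent)) latent <- stats::rnorm(n)
  registry <- config$registry
  energy <- simulate_energy(n, config, latent)
  intakes <- tibble::tibble(participant_id = ids, energy = energy)
  params <- registry[registry$name != "energy", ]
  for (i in seq_len(nrow(params))) {
    s <- sign(params$effect_score[i])
    density <- params$global_mean[i] *
      exp(config$intake_correlation * s * latent +
            config$intake_noise * stats::rnorm(n))
    scale <- if (params$energy_adjust[i]) energy / 1000 else 1
    intakes[[params$name[i]]] <- density * scale
  }
  list(intakes = intakes, latent = latent)
}

# General-characteristics covariates; all participants pass the default
# exclusion cascade by construction
simulate_covariates <- function(n, ids = seq_len(n)) {
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.55, 0.45))
  tibble::tibble(
    participant_id = ids,
    sex = sex,
    age = pmin(pmax(stats::rnorm(n, 40, 13.5), 19), 85),
    smoking = sample(c("never", "ex", "current"), n, replace = TRUE,
                     prob = c(0.62, 0.12, 0.26)),
    education_years = round(pmin(pmax(stats::rnorm(n, 11, 4.5), 0), 22)),
    physical_activity = stats::rlnorm(n, log(650), 0.8),
    pregnant = 0L, lactating = 0L, anti_obesity_meds = 0L
  )
}

# Baseline anthropometry with a DII gradient (dii_z = standardized DII)
simulate_baseline_anthro <- function(covars, dii_z, config) {
  n <- nrow(covars)
  male <- covars$sex == "male"
  slopes <- config$baseline_dii_slopes
  height <- pmin(pmax(
    stats::rnorm(n, ifelse(male, 1.74, 1.61), ifelse(male, 0.07, 0.06)),
    1.45), 2.05)
  bmi <- pmin(pmax(stats::rnorm(n, 27.2, 4.6) + slopes[["bmi"]] * dii_z,
                   16.5), 45)
  wc <- pmin(pmax(
    stats::rnorm(n, ifelse(male, 94, 90), ifelse(male, 11, 12)) +
      slopes[["wc"]] * dii_z, 55), 140)
  whr <- pmin(pmax(stats::rnorm(n, 0.92, 0.07) + slopes[["whr"]] * dii_z,
                   0.68), 1.15)
  tg <- pmin(pmax(stats::rlnorm(n, log(1.4), 0.40), 0.30), 8)
  hdl <- pmin(pmax(stats::rnorm(n, ifelse(male, 1.05, 1.25),
                                ifelse(male, 0.22, 0.25)), 0.55), 3)
  tibble::tibble(
    participant_id = covars$participant_id,
    weight = bmi * height^2, height = height,
    wc = wc, hc = wc / whr, tg = tg, hdl = hdl
  )
}

# Centered covariate contribution to every outcome logit; exactly the
# covariate set the analysis adjusts for
covariate_linear_predictor <- function(covars, pa_cat, config) {
  b <- config$covariate_logor
  b[["age"]] * (covars$age - 40) +
    b[["male"]] * (covars$sex == "male") +
    b[["energy"]] * (covars$energy - 2300) +
    b[["education_high"]] * (covars$education_years > 14) +
    b[["pa_moderate"]] * (pa_cat == "moderate") +
    b[["pa_high"]] * (pa_cat == "high") +
    b[["smoking_ex"]] * (covars$smoking == "ex") +
    b[["smoking_current"]] * (covars$smoking == "current")
}

#' Simulate binary change outcomes from the generative logistic model
#'
#' Each outcome's increase flag is Bernoulli with
#' \deqn{logit(p) = \alpha_o + \beta_{cov}'x + \gamma s +
#'   \theta_o[q, s]}
#' where s is the stratum, q the DII quartile, and \eqn{\theta_o} the
#' within-stratum quartile log-OR matrix of the configuration (the BMI
#' outcome additionally carries the per-allele SNP effects that define the
#' GRS weights).
#'
#' @param config A [sim_config()].
#' @param quartile Integer 1..4 DII quartile per participant.
#' @param stratum Binary 0/1 stratum per participant.
#' @param cov_lp Covariate contribution to the logit per participant.
#' @param snp_lp Per-allele SNP contribution (added to the BMI outcome only).
#' @param outcomes Which outcomes to draw.
#' @return Tibble of 0/1 flags named \code{increased_*}.
#' @export
simulate_outcomes <- function(config, quartile, stratum, cov_lp,
                              snp_lp = 0,
                              outcomes = c("bmi", "wc", "whr", "vai")) {
  n <- length(quartile)
  out <- tibble::tibble(.rows = n)
  for (o in outcomes) {
    cell <- config$cell_logor[[o]][cbind(quartile, stratum + 1)]
    lp <- config$intercepts[[o]] + cov_lp + config$stratum_logor * stratum +
      cell
    if (o == "bmi") lp <- lp + snp_lp
    out[[paste0("increased_", o)]] <-
      stats::rbinom(n, 1, stats::plogis(lp))
  }
  out
}

# Follow-up anthropometry consistent with the drawn increase flags: each
# measure moves by a half-normal magnitude in the direction its flag dictates,
# so recomputing deltas through the anthropometry module reproduces the flags
build_followup_anthro <- function(baseline, sex, flags, config) {
  n <- nrow(baseline)
  sc <- config$delta_scales
  mag <- function(scale) abs(stats::rnorm(n, 0, scale))
  sgn <- function(flag) ifelse(flag == 1, 1, -1)

  bmi_b <- baseline$weight / baseline$height^2
  whr_b <- baseline$wc / baseline$hc
  vai_b <- compute_vai(sex, baseline$wc, bmi_b, baseline$tg, baseline$hdl)

  bmi_f <- pmax(bmi_b + sgn(flags$increased_bmi) * mag(sc[["bmi"]]), 15)
  wc_f <- pmax(baseline$wc + sgn(flags$increased_wc) * mag(sc[["wc"]]), 50)
  whr_f <- pmax(whr_b + sgn(flags$increased_whr) * mag(sc[["whr"]]), 0.55)
  vai_f <- pmax(vai_b + sgn(flags$increased_vai) * mag(sc[["vai"]]),
                0.02 * vai_b)

  # TG is the free knob for VAI: VAI is proportional to TG given the rest
  vai_partial <- compute_vai(sex, wc_f, bmi_f, baseline$tg, baseline$hdl)
  tibble::tibble(
    participant_id = baseline$participant_id,
    weight = bmi_f * baseline$height^2,
    height = baseline$height,
    wc = wc_f,
    hc = wc_f / whr_f,
    tg = baseline$tg * vai_f / vai_partial,
    hdl = baseline$hdl
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws, in a fixed order under one seed: covariates, genotypes (HWE), the
#' latent diet factor and nutrient intakes, baseline anthropometry with its
#' DII gradient, the binary change outcomes from the configured logistic
#' effect model, and follow-up anthropometry consistent with those outcomes.
#' DII scores and quartiles are computed with the package's own scoring chain
#' (density adjustment to 1000 kcal against the configured registry), so the
#' generative quartile is exactly the quartile the analysis recovers.
#'
#' When \code{stratifier = "grs"}, the BMI-increase outcome is drawn first
#' (covariate and per-allele SNP effects only), the OR weights are estimated
#' from it exactly as the analysis does, and the resulting median split is the
#' stratum carrying the other outcomes' effects — mirroring a two-stage
#' weighted-GRS design.
#'
#' @param config A [sim_config()].
#' @return List of pipeline input tables — \code{phenotypes} (long, one row
#'   per participant and timepoint), \code{intakes}, \code{genotypes}
#'   (allele-pair calls), \code{dna_quality} — plus a \code{truth} list
#'   (latent factor, dii, quartile, stratum, flags, GRS weights if used) for
#'   validation.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  ids <- seq_len(n)

  covars <- simulate_covariates(n, ids)
  geno <- simulate_genotypes(n, config$snp_specs, ids)
  intk <- simulate_intakes(n, config, ids = ids)
  intakes <- intk$intakes

  adjusted <- energy_adjust_intakes(intakes, config$registry,
                                    method = "density",
                                    reference_energy = 1000)
  dii <- compute_dii(adjusted, config$registry)$dii
  quartile <- assign_quartiles(dii)
  q_int <- as.integer(quartile)
  dii_z <- (dii - mean(dii)) / stats::sd(dii)

  baseline <- simulate_baseline_anthro(covars, dii_z, config)

  pa_breaks <- stats::quantile(covars$physical_activity, c(1, 2) / 3,
                               names = FALSE)
  pa_cat <- cut(covars$physical_activity, c(-Inf, pa_breaks, Inf),
                labels = c("low", "moderate", "high"))
  covars_lp <- covariate_linear_predictor(
    cbind(covars, energy = intakes$energy), pa_cat, config)

  snp_lp <- as.numeric(
    as.matrix(geno$counts[, names(config$grs_per_allele_logor)]) %*%
      config$grs_per_allele_logor)

  truth <- list(latent = intk$latent, dii = dii, quartile = quartile)

  if (config$stratifier == "grs") {
    bmi_flag <- simulate_outcomes(config, q_int, rep(0L, n), covars_lp,
                                  snp_lp, outcomes = "bmi")$increased_bmi
    weights <- estimate_grs_weights(geno$counts, bmi_flag)
    stratum <- compute_grs(geno$counts, weights)$high_grs
    flags <- cbind(
      tibble::tibble(increased_bmi = bmi_flag),
      simulate_outcomes(config, q_int, stratum, covars_lp,
                        outcomes = c("wc", "whr", "vai")))
    truth$grs_weights <- weights
  } else {
    stratum <- if (config$stratifier == "none") {
      rep(0L, n)
    } else {
      code_genotype(geno$counts[[config$stratifier]], "dominant")
    }
    flags <- simulate_outcomes(config, q_int, stratum, covars_lp, snp_lp)
  }
  truth$stratum <- stratum
  truth$flags <- flags

  followup <- build_followup_anthro(baseline, covars$sex, flags, config)

  pheno_base <- dplyr::bind_cols(covars, baseline[, -1], timepoint = "baseline")
  pheno_fu <- dplyr::bind_cols(covars, followup[, -1], timepoint = "followup")
  phenotypes <- dplyr::bind_rows(pheno_base, pheno_fu)

  dna_quality <- tibble::tibble(
    participant_id = ids,
    a260_a280 = stats::runif(n, 1.75, 1.95)
  )

  list(phenotypes = phenotypes, intakes = intakes,
       genotypes = geno$calls, dna_quality = dna_quality, truth = truth)
}
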