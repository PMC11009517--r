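#' Join the pipeline input tables into one cohort table
#'
#' Produces the wide, one-row-per-participant table the exclusion cascade and
#' analysis operate on: constant characteristics from the baseline phenotype
#' row, measurement columns suffixed \code{_baseline} / \code{_followup},
#' nutrient intakes (including \code{energy}), genotype risk-allele counts,
#' and the DNA purity ratio.
#'
#' @param phenotypes Long phenotype table: \code{participant_id},
#'   \code{timepoint} ("baseline"/"followup"), \code{sex}, \code{age},
#'   \code{smoking}, \code{education_years}, \code{physical_activity},
#'   \code{pregnant}, \code{lactating}, \code{anti_obesity_meds},
#'   \code{weight}, \code{height}, \code{wc}, \code{hc}, \code{tg},
#'   \code{hdl}.
#' @param intakes Intake table: \code{participant_id}, \code{energy}, one
#'   column per dietary parameter.
#' @param genotypes Genotype table (allele pairs or 0/1/2 codes per SNP).
#' @param dna_quality Table with \code{participant_id}, \code{a260_a280}.
#' @param snp_specs SNP specification for genotype parsing.
#' @return One-row-per-participant tibble.
#' @export
assemble_cohort <- function(phenotypes, intakes, genotypes, dna_quality,
                            snp_specs = default_snp_specs()) {
  measures <- c("weight", "height", "wc", "hc", "tg", "hdl")
  constants <- setdiff(names(phenotypes), c(measures, "timepoint"))
  base <- phenotypes[phenotypes$timepoint == "baseline", , drop = FALSE]
  fu <- phenotypes[phenotypes$timepoint == "followup",
                   c("participant_id", measures), drop = FALSE]
  wide <- dplyr::left_join(
    base[, c(constants, measures)],
    fu, by = "participant_id", suffix = c("_baseline", "_followup"))
  counts <- parse_genotype_table(genotypes, snp_specs)
  wide <- dplyr::left_join(wide, intakes, by = "participant_id")
  wide <- dplyr::left_join(wide, counts, by = "participant_id")
  dplyr::left_join(wide, dna_quality[, c("participant_id", "a260_a280")],
                   by = "participant_id")
}

# Adjustment covariates used by every adjusted model, after
# derive_analysis_covariates() has added the derived codings
analysis_covariates <- function() {
  c("age", "sex", "energy", "education_high", "pa_cat", "smoking")
}

# Fixed categorical codings: education dichotomized at 14 years, physical
# activity cut at cohort tertiles of MET/min/wk, smoking with "never" as
# the reference level
derive_analysis_covariates <- function(data) {
  data$education_high <- as.integer(data$education_years > 14)
  pa_breaks <- stats::quantile(data$physical_activity, c(1, 2) / 3,
                               names = FALSE, na.rm = TRUE)
  data$pa_cat <- cut(data$physical_activity, c(-Inf, pa_breaks, Inf),
                     labels = c("low", "moderate", "high"))
  data$smoking <- factor(data$smoking, levels = c("never", "ex", "current"))
  data$sex <- factor(data$sex, levels = c("female", "male"))
  data
}

#' Build the analysis table from raw pipeline inputs
#'
#' Runs the full pre-model chain: join, exclusion cascade, DII scoring
#' (energy adjustment then scoring and quartile assignment), derived
#' adiposity measures and dichotomized changes at both timepoints, genotype
#' coding, HWE tests, GRS weights estimated from the BMI-increase outcome,
#' the GRS median split, and the fixed covariate codings.
#'
#' @param tables List with \code{phenotypes}, \code{intakes},
#'   \code{genotypes}, \code{dna_quality} (as produced by
#'   [simulate_cohort()] or read from disk).
#' @param registry DII parameter registry.
#' @param snp_specs SNP specification table.
#' @param energy_method,reference_energy Energy adjustment for DII scoring
#'   (see [energy_adjust_intakes()]).
#' @param ratio Waist ratio feeding the WHR change outcome ("whr" or
#'   "whtr").
#' @param lipid_units Units of TG/HDL for VAI.
#' @param min_parameters Minimum DII parameter coverage per participant.
#' @param rules Exclusion cascade (default [default_exclusion_rules()]).
#' @return List: \code{data} (analysis tibble), \code{audit} (participant
#'   flow), \code{hwe} (per-SNP chi-square tests), \code{grs_weights}.
#' @export
build_analysis_table <- function(tables,
                                 registry = default_dii_registry(),
                                 snp_specs = default_snp_specs(),
                                 energy_method = "density",
                                 reference_energy = 1000,
                                 ratio = c("whr", "whtr"),
                                 lipid_units = "mmol/L",
                                 min_parameters = nrow(registry),
                                 rules = default_exclusion_rules()) {
  ratio <- match.arg(ratio)
  cohort <- assemble_cohort(tables$phenotypes, tables$intakes,
                            tables$genotypes, tables$dna_quality, snp_specs)
  filtered <- apply_exclusions(cohort, rules)
  d <- filtered$cohort

  intake_cols <- c("participant_id", "energy",
                   intersect(registry$name, names(d)))
  adjusted <- energy_adjust_intakes(d[, unique(intake_cols)], registry,
                                    method = energy_method,
                                    reference_energy = reference_energy)
  dii <- compute_dii(adjusted, registry, min_parameters = min_parameters)
  d$dii <- dii$dii
  d$dii_quartile <- assign_quartiles(d$dii)

  mk_measures <- function(suffix) {
    derive_measures(tibble::tibble(
      participant_id = d$participant_id, sex = as.character(d$sex),
      weight = d[[paste0("weight", suffix)]],
      height = d[[paste0("height", suffix)]],
      wc = d[[paste0("wc", suffix)]], hc = d[[paste0("hc", suffix)]],
      tg = d[[paste0("tg", suffix)]], hdl = d[[paste0("hdl", suffix)]]
    ), lipid_units = lipid_units)
  }
  base_m <- mk_measures("_baseline")
  fu_m <- mk_measures("_followup")
  changes <- compute_changes(base_m, fu_m, ratio = ratio)
  d <- dplyr::bind_cols(
    d,
    stats::setNames(base_m[, c("bmi", "whr", "whtr", "vai")],
                    c("bmi_baseline", "whr_baseline", "whtr_baseline",
                      "vai_baseline")),
    changes[, -1])

  snps <- snp_specs$snp_id
  hwe <- lapply(snps, function(snp) {
    g <- d[[snp]]
    hwe_chi2(c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE)))
  })
  names(hwe) <- snps
  for (snp in snps) {
    d[[paste0(snp, "_dom")]] <- code_genotype(d[[snp]], "dominant")
  }
  weights <- estimate_grs_weights(d[, c("participant_id", snps)],
                                  d$increased_bmi, snp_ids = snps)
  grs <- compute_grs(d[, c("participant_id", snps)], weights)
  d$grs <- grs$grs
  d$high_grs <- grs$high_grs

  d <- derive_analysis_covariates(d)
  list(data = d, audit = filtered$audit, hwe = hwe, grs_weights = weights)
}

#' Run the full analysis pipeline
#'
#' Executes filter, DII scoring, genotype/GRS coding and the stratified
#' quartile-by-genotype logistic models for every requested outcome and
#' stratifier, plus the quartile descriptives — the complete table set of a
#' gene-diet interaction analysis.
#'
#' @param tables Raw input tables (see [build_analysis_table()]), e.g. from
#'   [simulate_cohort()].
#' @param outcomes Change outcomes to model (subset of bmi, wc, whr, vai).
#' @param stratifiers SNP ids (dominant model) and/or "grs".
#' @param covariates Adjustment covariates (default: age, sex, energy,
#'   education, physical-activity category, smoking).
#' @param ... Passed to [build_analysis_table()].
#' @return List: \code{analysis} (the [build_analysis_table()] bundle),
#'   \code{or_tables} (nested list by outcome then stratifier),
#'   \code{descriptives}, and \code{estimates} — a plain nested list of all
#'   numbers, stable under \code{jsonlite::toJSON()} for machine-readable
#'   export.
#' @export
run_pipeline <- function(tables,
                         outcomes = c("bmi", "wc", "whr", "vai"),
                         stratifiers = c(default_snp_specs()$snp_id, "grs"),
                         covariates = analysis_covariates(),
                         ...) {
  built <- build_analysis_table(tables, ...)
  d <- built$data

  or_tables <- list()
  estimates <- list(
    n = nrow(d),
    audit = as.list(stats::setNames(built$audit$n_remaining,
                                    built$audit$rule)),
    grs_weights = as.list(built$grs_weights),
    hwe_p = lapply(built$hwe, function(h) h$p)
  )
  for (o in outcomes) {
    outcome_col <- paste0("increased_", o)
    or_tables[[o]] <- list()
    for (s in stratifiers) {
      stratum_col <- if (s == "grs") "high_grs" else paste0(s, "_dom")
      tab <- fit_stratified_or_table(d, outcome_col,
                                     stratum_col = stratum_col,
                                     covariates = covariates)
      or_tables[[o]][[s]] <- tab
      estimates[[o]][[s]] <- list(
        or = stats::setNames(tab$cells$or,
                             paste0(tab$cells$quartile, ".S",
                                    tab$cells$stratum)),
        p_trend = as.list(tab$p_trend),
        p_interaction = tab$p_interaction
      )
    }
  }

  descriptives <- describe_by_quartile(
    d,
    continuous = c("age", "physical_activity", "bmi_baseline", "delta_bmi",
                   "wc_baseline", "delta_wc", "whr_baseline", "delta_whr",
                   "vai_baseline", "delta_vai", "energy"),
    categorical = c("sex", "smoking", "education_high"))

  list(analysis = built, or_tables = or_tables,
       descriptives = descriptives, estimates = estimates)
}

#' Quartile descriptive table
#'
#' Mean +/- SD with a one-way ANOVA p-value for continuous variables, and
#' percentages with a chi-square p-value (no continuity correction) for
#' categorical ones, per DII quartile.
#'
#' @param data Analysis table with a quartile factor column.
#' @param continuous,categorical Column names to summarize.
#' @param quartile_col Quartile factor column name.
#' @return Tibble: variable, type, one formatted column per quartile, p.
#' @export
describe_by_quartile <- function(data, continuous = character(),
                                 categorical = character(),
                                 quartile_col = "dii_quartile") {
  q <- data[[quartile_col]]
  if (any(table(q) == 0)) stop("Empty quartile", call. = FALSE)
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    m <- tapply(x, q, mean, na.rm = TRUE)
    s <- tapply(x, q, stats::sd, na.rm = TRUE)
    p <- summary(stats::aov(x ~ q))[[1]][["Pr(>F)"]][1]
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, type = "continuous",
      Q1 = sprintf("%.2f±%.2f", m[1], s[1]),
      Q2 = sprintf("%.2f±%.2f", m[2], s[2]),
      Q3 = sprintf("%.2f±%.2f", m[3], s[3]),
      Q4 = sprintf("%.2f±%.2f", m[4], s[4]),
      p = p)
  }
  for (v in categorical) {
    x <- data[[v]]
    tab <- table(x, q)
    top <- rownames(tab)[nrow(tab)]
    pct <- 100 * prop.table(tab, margin = 2)[nrow(tab), ]
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = paste0(v, " (% ", top, ")"), type = "categorical",
      Q1 = sprintf("%.1f", pct[1]), Q2 = sprintf("%.1f", pct[2]),
      Q3 = sprintf("%.1f", pct[3]), Q4 = sprintf("%.1f", pct[4]),
      p = p)
  }
  dplyr::bind_rows(rows)
}

#' Write / read the pipeline input tables
#'
#' All tables are UTF-8 tab-separated files with "." as the decimal mark and
#' the literal token "NA" for missing values, so tables written by the
#' simulator are read back unchanged by the analysis.
#'
#' @param tables List with \code{phenotypes}, \code{intakes},
#'   \code{genotypes}, \code{dna_quality}.
#' @param prefix Path prefix; files are written as
#'   \code{<prefix>_<table>.tsv}.
#' @return \code{write_cohort_tables}: the file paths, invisibly.
#' @export
write_cohort_tables <- function(tables, prefix) {
  nm <- c("phenotypes", "intakes", "genotypes", "dna_quality")
  paths <- stats::setNames(paste0(prefix, "_", nm, ".tsv"), nm)
  for (t in nm) readr::write_tsv(tables[[t]], paths[[t]], na = "NA")
  invisible(paths)
}

#' @rdname write_cohort_tables
#' @export
read_cohort_tables <- function(prefix) {
  nm <- c("phenotypes", "intakes", "genotypes", "dna_quality")
  out <- lapply(nm, function(t) {
    readr::read_tsv(paste0(prefix, "_", t, ".tsv"), na = "NA",
                    show_col_types = FALSE)
  })
  stats::setNames(out, nm)
}

#' Serialize pipeline estimates to JSON
#'
#' @param result A [run_pipeline()] bundle.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to file.
#' @export
estimates_json <- function(result, path = NULL) {
  json <- jsonlite::toJSON(result$estimates, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
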