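#' Default FTO SNP specification
#'
#' The three intronic FTO variants used throughout the pipeline, with their
#' major/minor alleles and the BMI-elevating risk allele (the minor allele by
#' default; configurable by editing the returned table). The minor-allele
#' frequencies are synthetic defaults for simulation, chosen above 0.2 as in
#' common-variant obesity panels.
#'
#' @return Tibble with columns \code{snp_id}, \code{major_allele},
#'   \code{minor_allele}, \code{risk_allele}, \code{maf}.
#' @export
default_snp_specs <- function() {
  tibble::tibble(
    snp_id = c("rs1121980", "rs1421085", "rs8050136"),
    major_allele = c("C", "T", "G"),
    minor_allele = c("T", "C", "A"),
    risk_allele = c("T", "C", "A"),
    maf = c(0.42, 0.40, 0.41)
  )
}

#' Count risk alleles in allele-pair genotype calls
#'
#' Converts string calls such as "TC" or "CC" into risk-allele counts 0/1/2.
#' NA calls propagate.
#'
#' @param calls Character vector of two-letter genotype calls.
#' @param risk_allele Single risk allele letter.
#' @param alleles Optional vector of the two legal alleles; calls containing
#'   anything else raise an error.
#' @return Integer vector of counts in \{0, 1, 2\}.
#' @export
count_risk_alleles <- function(calls, risk_allele, alleles = NULL) {
  out <- rep(NA_integer_, length(calls))
  ok <- !is.na(calls)
  if (any(nchar(calls[ok]) != 2)) {
    stop("Genotype calls must be two-letter strings", call. = FALSE)
  }
  split <- strsplit(calls[ok], "")
  if (!is.null(alleles)) {
    seen <- unique(unlist(split))
    bad <- setdiff(seen, alleles)
    if (length(bad) > 0) {
      stop("Unexpected allele(s) in genotype calls: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out[ok] <- vapply(split, function(a) sum(a == risk_allele), integer(1))
  out
}

#' Parse a genotype table into risk-allele counts
#'
#' Accepts per-SNP columns holding either numeric 0/1/2 risk-allele counts or
#' two-letter allele-pair strings, and returns a uniform count table.
#'
#' @param genotypes Data frame with \code{participant_id} and one column per
#'   SNP in \code{specs$snp_id}.
#' @param specs SNP specification table (see [default_snp_specs()]).
#' @return Tibble of integer risk-allele counts, one column per SNP.
#' @export
parse_genotype_table <- function(genotypes, specs = default_snp_specs()) {
  missing_snps <- setdiff(specs$snp_id, names(genotypes))
  if (length(missing_snps) > 0) {
    stop("Genotype table is missing SNP column(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(participant_id = genotypes$participant_id)
  for (i in seq_len(nrow(specs))) {
    snp <- specs$snp_id[i]
    col <- genotypes[[snp]]
    if (is.numeric(col)) {
      if (any(!col %in% c(0, 1, 2) & !is.na(col))) {
        stop("Numeric genotype codes for ", snp, " must be 0, 1 or 2",
             call. = FALSE)
      }
      out[[snp]] <- as.integer(col)
    } else {
      out[[snp]] <- count_risk_alleles(
        as.character(col), specs$risk_allele[i],
        alleles = c(specs$major_allele[i], specs$minor_allele[i])
      )
    }
  }
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparison of observed genotype counts against the
#' expected counts \code{n * (p^2, 2pq, q^2)} implied by the observed allele
#' frequencies, on 1 degree of freedom. For a monomorphic sample the statistic
#' is 0 (the data fit HWE trivially).
#'
#' @param counts Length-3 vector of genotype counts
#'   \code{(n_AA, n_Aa, n_aa)} where A is one of the two alleles.
#' @return List with \code{chi2}, \code{p} and the expected counts.
#' @export
hwe_chi2 <- function(counts) {
  if (length(counts) != 3 || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be three nonnegative genotype counts", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("All genotype counts are zero", call. = FALSE)
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  q_hat <- 1 - p_hat
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  nonzero <- expected > 0
  chi2 <- sum((counts[nonzero] - expected[nonzero])^2 / expected[nonzero])
  list(chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Code a genotype under an inheritance model
#'
#' @param g Risk-allele counts in \{0, 1, 2\} (NA propagates).
#' @param model "dominant" collapses carriers: 0 stays 0 (major-allele
#'   homozygote, the wild-type stratum), 1 and 2 both map to 1. "additive"
#'   returns the count unchanged.
#' @return Integer vector.
#' @export
code_genotype <- function(g, model = c("dominant", "additive")) {
  model <- match.arg(model)
  if (any(!g %in% c(0L, 1L, 2L) & !is.na(g))) {
    stop("g must be 0, 1 or 2", call. = FALSE)
  }
  if (model == "additive") return(as.integer(g))
  as.integer(g > 0)
}

#' Per-SNP odds ratio on a binary outcome
#'
#' Logistic regression of the outcome on the additive risk-allele count,
#' optionally with covariates; the OR is \code{exp} of the genotype
#' coefficient. Used to derive the OR weights of the genetic risk score.
#'
#' @param outcome Binary 0/1 vector.
#' @param g Additive risk-allele counts.
#' @param covariates Optional data frame of covariates entering the model.
#' @return List with \code{or}, \code{log_or}, \code{se}, \code{p}.
#' @export
fit_snp_or <- function(outcome, g, covariates = NULL) {
  if (length(unique(stats::na.omit(outcome))) < 2) {
    stop("Outcome must contain both classes", call. = FALSE)
  }
  dat <- data.frame(.y = outcome, .g = g)
  rhs <- ".g"
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".g", names(covariates)), collapse = " + ")
  }
  fit <- fit_logistic(stats::as.formula(paste(".y ~", rhs)), data = dat)
  b <- fit$coefficients[".g"]
  se <- sqrt(fit$vcov[".g", ".g"])
  list(or = unname(exp(b)), log_or = unname(b), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(b / se))))
}

#' Estimate GRS weights from the cohort
#'
#' Fits one per-SNP logistic regression of the BMI-increase outcome on the
#' additive risk-allele count and returns the odds ratios as weights. A
#' warning (not a silent flip) is emitted if a declared risk allele comes out
#' protective (OR < 1).
#'
#' @param geno_counts Risk-allele count table from [parse_genotype_table()].
#' @param outcome Binary BMI-increase outcome aligned with
#'   \code{geno_counts}.
#' @param snp_ids SNPs to weight (default: all count columns).
#' @return Named numeric vector of OR weights.
#' @export
estimate_grs_weights <- function(geno_counts, outcome, snp_ids = NULL) {
  if (is.null(snp_ids)) {
    snp_ids <- setdiff(names(geno_counts), "participant_id")
  }
  weights <- vapply(snp_ids, function(snp) {
    fit_snp_or(outcome, geno_counts[[snp]])$or
  }, numeric(1))
  low <- weights < 1
  if (any(low)) {
    warning("Declared risk allele has OR < 1 for: ",
            paste(snp_ids[low], collapse = ", "),
            " (weights kept as estimated; check risk-allele orientation)",
            call. = FALSE)
  }
  weights
}

#' OR-weighted genetic risk score
#'
#' \deqn{GRS = \sum_j OR_j \times g_j} where \code{g_j} is the risk-allele
#' count for SNP j and \code{OR_j} its odds-ratio weight. Note the weights are
#' the raw odds ratios, not log-odds ratios. Participants with any missing
#' call get an NA score (strict missing policy) and are excluded from
#' GRS-stratified analyses. The high-GRS indicator is 1 for scores at or above
#' the cohort median (ties go to the high group).
#'
#' @param geno_counts Risk-allele count table from [parse_genotype_table()].
#' @param weights Named OR weights covering all SNP columns used.
#' @return Tibble: \code{participant_id}, \code{grs}, \code{high_grs}.
#' @export
compute_grs <- function(geno_counts, weights) {
  snp_ids <- names(weights)
  missing_snps <- setdiff(snp_ids, names(geno_counts))
  if (length(missing_snps) > 0) {
    stop("Genotype table lacks weighted SNP(s): ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  if (any(weights <= 0)) stop("All OR weights must be > 0", call. = FALSE)
  g <- as.matrix(geno_counts[, snp_ids, drop = FALSE])
  grs <- as.numeric(g %*% weights)
  grs[apply(g, 1, anyNA)] <- NA_real_
  med <- stats::median(grs, na.rm = TRUE)
  tibble::tibble(
    participant_id = geno_counts$participant_id,
    grs = grs,
    high_grs = ifelse(is.na(grs), NA_integer_, as.integer(grs >= med))
  )
}
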