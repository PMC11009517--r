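#' Combine DII quartile and genotype stratum into the 8-group coding
#'
#' The stratified analysis enters exposure as a single factor over the 4 x 2
#' grid of DII quartile by genotype stratum (dominant-model carrier status or
#' GRS median split). The reference level — the omitted dummy — is Q1 in the
#' wild-type / low-GRS stratum.
#'
#' @param quartile Factor with levels Q1..Q4.
#' @param stratum Binary 0/1 (0 = wild-type or low-GRS stratum).
#' @return Factor with 8 levels \code{Q1.S0 ... Q4.S0, Q1.S1 ... Q4.S1};
#'   missing quartile or stratum gives NA.
#' @export
build_eight_groups <- function(quartile, stratum) {
  if (!all(stats::na.omit(as.character(quartile)) %in%
           c("Q1", "Q2", "Q3", "Q4"))) {
    stop("quartile must take values Q1..Q4", call. = FALSE)
  }
  if (!all(stats::na.omit(stratum) %in% c(0, 1))) {
    stop("stratum must be binary 0/1", call. = FALSE)
  }
  lev <- c(paste0("Q", 1:4, ".S0"), paste0("Q", 1:4, ".S1"))
  factor(ifelse(is.na(quartile) | is.na(stratum), NA,
                paste0(as.character(quartile), ".S", stratum)),
         levels = lev)
}

# Build "y ~ rhs" formula from character pieces
build_formula <- function(outcome, terms) {
  stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
}

#' Trend test across DII quartiles within one stratum
#'
#' Logistic model with the quartile entered as a single ordinal covariate
#' (1, 2, 3, 4) plus adjustment covariates; the p-value is the Wald test of
#' the ordinal coefficient.
#'
#' @param data Analysis table (one stratum's rows).
#' @param outcome Name of the binary outcome column.
#' @param quartile_col Name of the quartile factor column.
#' @param covariates Character vector of adjustment covariate column names.
#' @return List with \code{p}, \code{slope} (log-odds per quartile) and
#'   \code{se}.
#' @export
p_trend <- function(data, outcome, quartile_col = "dii_quartile",
                    covariates = character()) {
  data$.q_ord <- as.integer(data[[quartile_col]])
  fit <- fit_logistic(build_formula(outcome, c(".q_ord", covariates)), data)
  list(p = wald_p(fit, ".q_ord"),
       slope = unname(fit$coefficients[".q_ord"]),
       se = sqrt(fit$vcov[".q_ord", ".q_ord"]))
}

#' Interaction test between DII quartile and genotype stratum
#'
#' Logistic model with main effects for the ordinal quartile (1..4), the
#' binary stratum, and adjustment covariates, plus the quartile-by-stratum
#' product term. By default the p-value is the Wald test of the product term;
#' \code{quartile_form = "categorical"} instead enters quartile as a 3-dummy
#' factor and tests the 3-df interaction block by likelihood ratio.
#'
#' @inheritParams p_trend
#' @param stratum_col Name of the binary stratum column.
#' @param quartile_form "ordinal" (default) or "categorical".
#' @return List with \code{p} and, for the ordinal form, the interaction
#'   coefficient and its SE.
#' @export
p_interaction <- function(data, outcome, quartile_col = "dii_quartile",
                          stratum_col = "stratum",
                          covariates = character(),
                          quartile_form = c("ordinal", "categorical")) {
  quartile_form <- match.arg(quartile_form)
  data$.s <- data[[stratum_col]]
  if (quartile_form == "ordinal") {
    data$.q_ord <- as.integer(data[[quartile_col]])
    fit <- fit_logistic(
      build_formula(outcome, c(".q_ord", ".s", ".q_ord:.s", covariates)), data)
    list(p = wald_p(fit, ".q_ord:.s"),
         coef = unname(fit$coefficients[".q_ord:.s"]),
         se = sqrt(fit$vcov[".q_ord:.s", ".q_ord:.s"]))
  } else {
    data$.q <- data[[quartile_col]]
    f0 <- fit_logistic(build_formula(outcome, c(".q", ".s", covariates)), data)
    f1 <- fit_logistic(build_formula(outcome, c(".q", ".s", ".q:.s",
                                                covariates)), data)
    lrt <- stats::anova(f0$fit, f1$fit, test = "Chisq")
    list(p = lrt$`Pr(>Chi)`[2])
  }
}

#' Stratified OR table over DII quartiles and a genotype stratifier
#'
#' Fits the adjusted 8-group logistic model (see [build_eight_groups()]) and
#' reports, in the layout of gene-diet interaction papers, the within-stratum
#' odds ratios against each stratum's own Q1 cell:
#' \itemize{
#'   \item stratum 0 (wild-type / low GRS): OR of Qk.S0 vs the model reference
#'     Q1.S0, straight from the dummy coefficient;
#'   \item stratum 1 (carrier / high GRS): OR of Qk.S1 vs Q1.S1, a linear
#'     contrast of two dummies with a delta-method Wald CI.
#' }
#' Each stratum's Q1 cell is the fixed reference with OR 1. Per-stratum trend
#' tests ([p_trend()]) and the table-wide interaction test
#' ([p_interaction()]) are attached.
#'
#' @param data Analysis table with the outcome, quartile factor, binary
#'   stratum and covariates; rows with NA in any of these are dropped.
#' @param outcome Name of the binary outcome column.
#' @param stratum_col Name of the binary 0/1 stratum column.
#' @param quartile_col Name of the quartile factor column.
#' @param covariates Character vector of adjustment covariate column names.
#' @param level Confidence level (default 0.95).
#' @return List of class \code{stratified_or_table}: \code{cells} (tibble of
#'   stratum, quartile, or, ci_low, ci_high, p, n), \code{p_trend} (length-2
#'   named vector), \code{p_interaction}, \code{fit}.
#' @export
fit_stratified_or_table <- function(data, outcome,
                                    stratum_col = "stratum",
                                    quartile_col = "dii_quartile",
                                    covariates = character(),
                                    level = 0.95) {
  used <- c(outcome, quartile_col, stratum_col, covariates)
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  data$.grp <- build_eight_groups(data[[quartile_col]], data[[stratum_col]])
  if (any(table(data$.grp) == 0)) {
    stop("Empty quartile-by-stratum cell; cannot fit the 8-group model",
         call. = FALSE)
  }
  fit <- fit_logistic(build_formula(outcome, c(".grp", covariates)), data)

  cell_rows <- list()
  n_by_grp <- table(data$.grp)
  for (s in 0:1) {
    for (q in 1:4) {
      lab <- paste0("Q", q, ".S", s)
      if (q == 1) {
        est <- list(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_)
      } else if (s == 0) {
        est <- or_contrast(fit, paste0(".grp", lab), level = level)
      } else {
        ctr <- stats::setNames(c(1, -1),
                               c(paste0(".grp", lab), ".grpQ1.S1"))
        est <- or_contrast(fit, ctr, level = level)
      }
      cell_rows[[length(cell_rows) + 1]] <- tibble::tibble(
        stratum = s, quartile = paste0("Q", q),
        or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
        p = est$p, n = as.integer(n_by_grp[[lab]])
      )
    }
  }

  trend <- vapply(0:1, function(s) {
    p_trend(data[data[[stratum_col]] == s, , drop = FALSE], outcome,
            quartile_col, covariates)$p
  }, numeric(1))
  names(trend) <- c("S0", "S1")
  inter <- p_interaction(data, outcome, quartile_col, stratum_col, covariates)

  structure(
    list(cells = dplyr::bind_rows(cell_rows),
         p_trend = trend, p_interaction = inter$p, fit = fit),
    class = "stratified_or_table"
  )
}

#' @export
print.stratified_or_table <- function(x, ...) {
  cells <- x$cells
  cells$or_ci <- ifelse(
    is.na(cells$ci_low), "1 (ref)",
    sprintf("%.2f (%.2f-%.2f)", cells$or, cells$ci_low, cells$ci_high))
  wide <- tidyr::pivot_wider(
    cells[, c("stratum", "quartile", "or_ci")],
    names_from = "quartile", values_from = "or_ci")
  wide$p_trend <- signif(x$p_trend, 2)
  print(as.data.frame(wide), row.names = FALSE)
  cat("P interaction:", signif(x$p_interaction, 2), "\n")
  invisible(x)
}

#' Baseline linear association of an adiposity measure with DII, by stratum
#'
#' Ordinary least squares of the baseline measure on the continuous DII score
#' within each genotype stratum, plus a pooled model with a DII-by-stratum
#' product term whose t-test gives the interaction p-value.
#'
#' @param data Analysis table.
#' @param measure Name of the continuous baseline measure column.
#' @param dii_col Name of the continuous DII column.
#' @param stratum_col Name of the binary stratum column.
#' @param covariates Adjustment covariate column names.
#' @return List with \code{by_stratum} (tibble: stratum, slope, se, p) and
#'   \code{p_interaction}.
#' @export
baseline_linear_trend <- function(data, measure, dii_col = "dii",
                                  stratum_col = "stratum",
                                  covariates = character()) {
  used <- c(measure, dii_col, stratum_col, covariates)
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  data$.dii <- data[[dii_col]]
  data$.s <- data[[stratum_col]]

  rows <- lapply(0:1, function(s) {
    d <- data[data$.s == s, , drop = FALSE]
    fit <- stats::lm(build_formula(measure, c(".dii", covariates)), data = d)
    sm <- summary(fit)$coefficients
    tibble::tibble(stratum = s, slope = sm[".dii", "Estimate"],
                   se = sm[".dii", "Std. Error"],
                   p = sm[".dii", "Pr(>|t|)"])
  })
  pooled <- stats::lm(build_formula(measure, c(".dii", ".s", ".dii:.s",
                                               covariates)), data = data)
  sm <- summary(pooled)$coefficients
  list(by_stratum = dplyr::bind_rows(rows),
       p_interaction = sm[".dii:.s", "Pr(>|t|)"])
}
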