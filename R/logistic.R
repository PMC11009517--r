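#' Maximum-likelihood logistic regression
#'
#' Thin, checked wrapper around \code{stats::glm} (binomial family, logit
#' link, iteratively reweighted least squares) used by every model in the
#' package. Convergence is tightened to a coefficient-scale tolerance of
#' 1e-10 with at most 100 iterations. The fit is rejected — rather than
#' silently returned — on rank deficiency (aliased columns are named), on
#' non-convergence, and on apparent complete separation (runaway
#' coefficients).
#'
#' @param formula Model formula with a binary 0/1 response.
#' @param data Data frame.
#' @param weights Optional case weights (used for grouped binomial data).
#' @return List of class \code{diigrs_logit}: \code{coefficients},
#'   \code{vcov}, \code{n}, \code{converged}, and the underlying \code{fit}.
#' @export
fit_logistic <- function(formula, data, weights = NULL) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(stats::na.omit(y))) < 2) {
    stop("Outcome must contain both classes", call. = FALSE)
  }
  args <- list(formula = formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!is.null(weights)) {
    data$.w <- weights
    args$data <- data
    args$weights <- quote(.w)
  }
  fit <- do.call(stats::glm, args)
  if (!fit$converged) {
    stop("Logistic regression did not converge within 100 IRLS iterations",
         call. = FALSE)
  }
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop("Rank-deficient design; aliased terms: ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "), call. = FALSE)
  }
  big <- abs(coefs) > 15
  if (any(big)) {
    stop("Apparent separation; runaway coefficient(s): ",
         paste(names(coefs)[big], collapse = ", "), call. = FALSE)
  }
  structure(
    list(coefficients = coefs, vcov = stats::vcov(fit),
         n = stats::nobs(fit), converged = fit$converged, fit = fit),
    class = "diigrs_logit"
  )
}

#' Odds ratio and Wald CI for a linear contrast of coefficients
#'
#' @param fit A \code{diigrs_logit} object.
#' @param contrast Either a single coefficient name or a named numeric
#'   contrast vector over coefficients.
#' @param level Confidence level (default 0.95).
#' @return List with \code{or}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{log_or}, \code{se}.
#' @export
or_contrast <- function(fit, contrast, level = 0.95) {
  cn <- names(fit$coefficients)
  if (is.character(contrast) && length(contrast) == 1) {
    v <- stats::setNames(numeric(length(cn)), cn)
    if (!contrast %in% cn) {
      stop("No coefficient named '", contrast, "'", call. = FALSE)
    }
    v[contrast] <- 1
  } else {
    v <- stats::setNames(numeric(length(cn)), cn)
    bad <- setdiff(names(contrast), cn)
    if (length(bad) > 0) {
      stop("Contrast names not in model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    v[names(contrast)] <- contrast
  }
  est <- sum(v * fit$coefficients)
  se <- sqrt(drop(t(v) %*% fit$vcov %*% v))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(est), ci_low = exp(est - zq * se),
       ci_high = exp(est + zq * se),
       p = 2 * stats::pnorm(-abs(est / se)),
       log_or = est, se = se)
}

# Wald p-value for a single coefficient of a diigrs_logit fit
wald_p <- function(fit, term) {
  b <- fit$coefficients[term]
  se <- sqrt(fit$vcov[term, term])
  unname(2 * stats::pnorm(-abs(b / se)))
}
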