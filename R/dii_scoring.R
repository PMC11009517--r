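#' Energy-adjust nutrient intakes
#'
#' Rescales each energy-adjustable dietary parameter to a common reference
#' energy intake before DII scoring. Two standard methods are supported:
#'
#' \describe{
#'   \item{density}{nutrient density: \code{x * reference_energy / energy};
#'     with \code{reference_energy = 1000} this is the familiar
#'     amount-per-1000-kcal scale.}
#'   \item{residual}{the residual method: each parameter is regressed on
#'     energy across the cohort and the adjusted intake is the participant's
#'     residual plus the predicted intake at \code{reference_energy}. Requires
#'     the full cohort in one call, since the calibration is cohort-wide.}
#' }
#'
#' Energy itself and any parameter with \code{energy_adjust = FALSE} in the
#' registry pass through unchanged.
#'
#' @param intakes Data frame with \code{participant_id}, an energy column
#'   (kcal/day) and one column per dietary parameter (daily amounts, native
#'   units).
#' @param registry DII parameter registry (see [default_dii_registry()]).
#' @param method "density" (default) or "residual".
#' @param reference_energy Reference energy in kcal/day (default 1000).
#' @param energy_col Name of the energy column (default "energy").
#' @return The intake table with adjustable parameter columns rescaled.
#' @export
energy_adjust_intakes <- function(intakes, registry,
                                  method = c("density", "residual"),
                                  reference_energy = 1000,
                                  energy_col = "energy") {
  method <- match.arg(method)
  registry <- validate_dii_registry(registry)
  if (!energy_col %in% names(intakes)) {
    stop("Energy column '", energy_col, "' not found in intake table",
         call. = FALSE)
  }
  energy <- intakes[[energy_col]]
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    bad <- intakes$participant_id[!is.finite(energy) | energy <= 0]
    stop("Non-positive or missing energy intake for participant(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  param_cols <- setdiff(names(intakes), c("participant_id", energy_col))
  unknown <- setdiff(param_cols, registry$name)
  if (length(unknown) > 0) {
    stop("Unknown dietary parameter(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  adjustable <- registry$name[registry$energy_adjust]
  adjustable <- setdiff(intersect(adjustable, param_cols), energy_col)

  out <- intakes
  for (p in adjustable) {
    x <- out[[p]]
    if (method == "density") {
      out[[p]] <- x * reference_energy / energy
    } else {
      fit <- stats::lm(x ~ energy)
      pred_ref <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * reference_energy)
      out[[p]] <- unname(stats::residuals(fit)) + pred_ref
    }
  }
  out
}

#' Standardize an intake against its global reference
#'
#' @param x Intake amount (same unit and adjustment scale as the reference).
#' @param global_mean,global_sd Global reference mean and SD; \code{global_sd}
#'   must be positive.
#' @return The z-score \code{(x - global_mean) / global_sd}.
#' @export
dii_z_score <- function(x, global_mean, global_sd) {
  if (any(!is.finite(global_sd)) || any(global_sd <= 0)) {
    stop("global_sd must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("Intake values must be finite", call. = FALSE)
  }
  (x - global_mean) / global_sd
}

#' Centered percentile transform of a z-score
#'
#' Converts a z-score to its standard-normal percentile and centers it on
#' zero: \code{2 * pnorm(z) - 1}. The result lies strictly in (-1, 1), is 0 at
#' the global mean, and is antisymmetric in z. This transform removes the
#' right-skew of raw intake distributions before the effect scores are
#' applied.
#'
#' @param z A finite z-score (vectorized).
#' @return Centered percentile in (-1, 1).
#' @export
centered_percentile <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  2 * stats::pnorm(z) - 1
}

#' Score one dietary parameter
#'
#' Per-parameter DII contribution: the centered percentile of the standardized
#' intake, multiplied by the parameter's inflammatory effect score.
#'
#' @param x Intake amount.
#' @param spec One registry row (list or one-row data frame with
#'   \code{global_mean}, \code{global_sd}, \code{effect_score}).
#' @return Signed score in \code{[-|w|, |w|]} for effect score \code{w}.
#' @export
score_dii_parameter <- function(x, spec) {
  z <- dii_z_score(x, spec$global_mean, spec$global_sd)
  centered_percentile(z) * spec$effect_score
}

#' Per-parameter DII score matrix for a cohort
#'
#' @param intakes Intake table (already energy-adjusted if the registry's
#'   references are on an adjusted scale): \code{participant_id} plus one
#'   column per parameter.
#' @param registry DII parameter registry.
#' @return A tibble with \code{participant_id} and one score column per
#'   registry parameter present in \code{intakes}; NA intakes give NA scores.
#' @keywords internal
dii_parameter_scores <- function(intakes, registry) {
  registry <- validate_dii_registry(registry)
  present <- intersect(registry$name, names(intakes))
  out <- tibble::tibble(participant_id = intakes$participant_id)
  for (p in present) {
    spec <- registry[registry$name == p, ]
    x <- intakes[[p]]
    s <- rep(NA_real_, length(x))
    ok <- is.finite(x)
    s[ok] <- centered_percentile((x[ok] - spec$global_mean) / spec$global_sd) *
      spec$effect_score
    out[[p]] <- s
  }
  out
}

#' Compute the Dietary Inflammatory Index
#'
#' For each participant, every available dietary parameter is standardized
#' against its global reference (z-score), transformed to a centered
#' percentile, multiplied by the parameter's inflammatory effect score, and
#' the per-parameter scores are summed into the overall DII. Higher DII means
#' a more pro-inflammatory diet.
#'
#' Parameters absent from the intake table (or NA for a participant)
#' contribute 0 and are not counted in \code{n_parameters_used}. Participants
#' covering fewer than \code{min_parameters} parameters are flagged
#' (\code{scored = FALSE}) and given an NA total rather than a misleading
#' partial score.
#'
#' @param intakes Intake table: \code{participant_id} plus one column per
#'   dietary parameter, on the same adjustment scale as the registry
#'   references (see [energy_adjust_intakes()]).
#' @param registry DII parameter registry.
#' @param min_parameters Minimum number of non-missing parameters required to
#'   score a participant. Defaults to all parameters in the registry.
#' @return Tibble with \code{participant_id}, \code{dii},
#'   \code{n_parameters_used}, \code{scored}.
#' @export
compute_dii <- function(intakes, registry, min_parameters = nrow(registry)) {
  registry <- validate_dii_registry(registry)
  scores <- dii_parameter_scores(intakes, registry)
  score_mat <- as.matrix(scores[, setdiff(names(scores), "participant_id"),
                                drop = FALSE])
  n_used <- rowSums(!is.na(score_mat))
  total <- rowSums(score_mat, na.rm = TRUE)
  scored <- n_used >= min_parameters
  total[!scored] <- NA_real_
  tibble::tibble(
    participant_id = intakes$participant_id,
    dii = total,
    n_parameters_used = as.integer(n_used),
    scored = scored
  )
}

#' Assign empirical quartiles
#'
#' Cuts a score vector at its 25th/50th/75th empirical percentiles
#' (\code{quantile()} type 7). Q1 holds the lowest (most anti-inflammatory)
#' scores. Values tied with a cut point fall in the lower quartile, so the
#' assignment is deterministic given the data.
#'
#' @param x Numeric vector with at least 4 distinct finite values.
#' @return Factor with levels Q1..Q4, same length as \code{x} (NA in, NA out).
#' @export
assign_quartiles <- function(x) {
  finite <- x[is.finite(x)]
  if (length(unique(finite)) < 4) {
    stop("Need at least 4 distinct values to assign quartiles", call. = FALSE)
  }
  breaks <- stats::quantile(finite, probs = c(0.25, 0.5, 0.75),
                            names = FALSE, type = 7)
  if (anyDuplicated(breaks)) {
    stop("Quartile cut points are not distinct (too many ties)", call. = FALSE)
  }
  cut(x, breaks = c(-Inf, breaks, Inf),
      labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
}
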