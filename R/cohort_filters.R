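#' Build an exclusion rule
#'
#' @param name Short identifier for the audit trail.
#' @param predicate Function taking the cohort table and returning a logical
#'   vector, TRUE where the participant is to be excluded. NA results are
#'   treated as TRUE (missing data required by a rule excludes at that rule).
#' @param description Human-readable account of the rule.
#' @return An object of class \code{exclusion_rule}.
#' @export
exclusion_rule <- function(name, predicate, description = name) {
  stopifnot(is.character(name), is.function(predicate))
  structure(list(name = name, predicate = predicate,
                 description = description),
            class = "exclusion_rule")
}

#' Default exclusion cascade
#'
#' The ordered eligibility rules applied to a joined cohort table, mirroring
#' the recruitment design of adult prospective nutrition cohorts:
#' \enumerate{
#'   \item minors (age <= 18 years);
#'   \item anti-obesity medication use, or missing dietary or anthropometric
#'     data;
#'   \item missing DNA, or DNA purity (A260/A280) outside the open interval
#'     (1.7, 2): 1.7 and 2 themselves are excluded;
#'   \item implausible energy intake: below 800 or above 4200 kcal/day
#'     (800 and 4200 themselves are retained);
#'   \item pregnancy;
#'   \item lactation.
#' }
#'
#' @return List of [exclusion_rule()] objects in application order.
#' @export
default_exclusion_rules <- function() {
  anthro_cols <- c("weight_baseline", "height_baseline", "wc_baseline",
                   "hc_baseline", "weight_followup", "wc_followup",
                   "hc_followup")
  list(
    exclusion_rule(
      "age_18_or_younger",
      function(d) is.na(d$age) | d$age <= 18,
      "Aged 18 years or younger"
    ),
    exclusion_rule(
      "meds_or_missing_data",
      function(d) {
        present <- intersect(anthro_cols, names(d))
        miss <- is.na(d$energy)
        for (col in present) miss <- miss | is.na(d[[col]])
        (!is.na(d$anti_obesity_meds) & d$anti_obesity_meds == 1) |
          is.na(d$anti_obesity_meds) | miss
      },
      "Anti-obesity medication or missing dietary/anthropometric data"
    ),
    exclusion_rule(
      "dna_quality",
      function(d) is.na(d$a260_a280) | d$a260_a280 <= 1.7 | d$a260_a280 >= 2,
      "No DNA sample or A260/A280 purity outside (1.7, 2)"
    ),
    exclusion_rule(
      "implausible_energy",
      function(d) is.na(d$energy) | d$energy < 800 | d$energy > 4200,
      "Energy intake < 800 or > 4200 kcal/day"
    ),
    exclusion_rule(
      "pregnant",
      function(d) !is.na(d$pregnant) & d$pregnant == 1,
      "Pregnant at baseline"
    ),
    exclusion_rule(
      "lactating",
      function(d) !is.na(d$lactating) & d$lactating == 1,
      "Lactating at baseline"
    )
  )
}

#' Apply an exclusion cascade with a participant-flow audit
#'
#' Rules are applied strictly in order; a participant is counted against the
#' first rule that excludes them and never re-tested by later rules, matching
#' how participant-flow diagrams report grouped sequential counts. Final
#' membership is order-invariant (a participant failing any rule is excluded
#' regardless of order); only the per-step attribution depends on order.
#'
#' @param cohort Joined cohort table, one row per participant.
#' @param rules List of [exclusion_rule()]s (default
#'   [default_exclusion_rules()]).
#' @return List with \code{cohort} (retained rows) and \code{audit}, a tibble
#'   of \code{step}, \code{rule}, \code{n_excluded}, \code{n_remaining}
#'   satisfying n_input = n_remaining + sum(n_excluded).
#' @export
apply_exclusions <- function(cohort, rules = default_exclusion_rules()) {
  keep <- rep(TRUE, nrow(cohort))
  steps <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    rule <- rules[[i]]
    hit <- rule$predicate(cohort)
    if (length(hit) != nrow(cohort)) {
      stop("Rule '", rule$name, "' returned a predicate of wrong length",
           call. = FALSE)
    }
    hit[is.na(hit)] <- TRUE
    drop_now <- keep & hit
    keep <- keep & !hit
    steps[[i]] <- tibble::tibble(
      step = i, rule = rule$name,
      n_excluded = sum(drop_now), n_remaining = sum(keep)
    )
  }
  list(cohort = cohort[keep, , drop = FALSE],
       audit = dplyr::bind_rows(steps))
}

#' Participant-flow arithmetic from printed counts
#'
#' Replays an exclusion cascade given only the starting population size and
#' the per-step exclusion counts, as printed in a study-flow description, and
#' returns the same audit structure as [apply_exclusions()].
#'
#' @param n_start Starting population size.
#' @param exclusions Named numeric vector of per-step exclusion counts, in
#'   order.
#' @return Audit tibble of \code{step}, \code{rule}, \code{n_excluded},
#'   \code{n_remaining}.
#' @export
flow_from_counts <- function(n_start, exclusions) {
  if (is.null(names(exclusions)) || any(names(exclusions) == "")) {
    stop("exclusions must be a fully named vector", call. = FALSE)
  }
  remaining <- n_start - cumsum(exclusions)
  if (any(remaining < 0)) {
    stop("Exclusion counts exceed the starting population", call. = FALSE)
  }
  tibble::tibble(
    step = seq_along(exclusions),
    rule = names(exclusions),
    n_excluded = as.numeric(exclusions),
    n_remaining = as.numeric(remaining)
  )
}
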