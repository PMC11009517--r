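#' Read a DII parameter reference table
#'
#' The Dietary Inflammatory Index (DII) is computed against a fixed reference
#' table: for every dietary parameter a global reference mean and SD of daily
#' intake and a signed inflammatory effect score (positive = pro-inflammatory,
#' negative = anti-inflammatory). This reads such a table from a tab-separated
#' file with columns \code{name}, \code{unit}, \code{global_mean},
#' \code{global_sd}, \code{effect_score} and \code{energy_adjust} (logical:
#' whether the parameter is energy-adjusted before scoring).
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per dietary parameter, validated by
#'   [validate_dii_registry()].
#' @seealso [default_dii_registry()] for the registry shipped with the package.
#' @export
read_dii_registry <- function(path) {
  registry <- readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      unit = readr::col_character(),
      global_mean = readr::col_double(),
      global_sd = readr::col_double(),
      effect_score = readr::col_double(),
      energy_adjust = readr::col_logical()
    )
  )
  validate_dii_registry(registry)
}

#' Built-in synthetic DII parameter registry
#'
#' Returns the registry shipped with the package: the 37 dietary parameters
#' used throughout (energy, macronutrients, fatty-acid classes, vitamins,
#' minerals, caffeine, tea, flavonoid classes, garlic, onion, pepper).
#'
#' The reference means, SDs and effect scores in this file are
#' \strong{synthetic placeholders}: they are plausible in sign and rough
#' magnitude but are not the literature-derived global reference values, which
#' are not redistributed here. Analyses of real data should supply their own
#' table via [read_dii_registry()].
#'
#' @return A 37-row registry tibble.
#' @export
#' @examples
#' reg <- default_dii_registry()
#' nrow(reg) # 37
default_dii_registry <- function() {
  path <- system.file("extdata", "dii_registry_synthetic.tsv",
                      package = "diigrs", mustWork = TRUE)
  read_dii_registry(path)
}

#' Validate a DII parameter registry
#'
#' Checks the structural invariants: required columns, unique parameter names,
#' strictly positive global SDs and finite effect scores.
#'
#' @param registry A data frame as returned by [read_dii_registry()].
#' @return The registry, invisibly coerced to a tibble, if valid; otherwise an
#'   error.
#' @export
validate_dii_registry <- function(registry) {
  required <- c("name", "unit", "global_mean", "global_sd",
                "effect_score", "energy_adjust")
  missing_cols <- setdiff(required, names(registry))
  if (length(missing_cols) > 0) {
    stop("DII registry is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(registry$name)) {
    dup <- unique(registry$name[duplicated(registry$name)])
    stop("Duplicate parameter names in DII registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(registry$global_sd)) || any(registry$global_sd <= 0)) {
    stop("All global_sd values must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(registry$effect_score))) {
    stop("All effect_score values must be finite", call. = FALSE)
  }
  if (any(!is.finite(registry$global_mean))) {
    stop("All global_mean values must be finite", call. = FALSE)
  }
  tibble::as_tibble(registry)
}
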