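#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in m.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0) ||
      any(!is.finite(height)) || any(height <= 0)) {
    stop("weight and height must be finite and > 0", call. = FALSE)
  }
  weight / height^2
}

#' Waist ratios
#'
#' Computes both the waist-to-hip ratio (WC/HC) and the waist-to-height ratio
#' (WC/height). Both are returned; which one feeds the change-in-WHR analysis
#' is a configuration choice (default waist-to-hip).
#'
#' @param wc Waist circumference, cm.
#' @param hc Hip circumference, cm.
#' @param height_cm Height, cm.
#' @return Tibble with columns \code{whr} (waist/hip) and \code{whtr}
#'   (waist/height).
#' @export
compute_waist_ratios <- function(wc, hc, height_cm) {
  if (any(!is.finite(hc)) || any(hc <= 0) ||
      any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("hip circumference and height must be finite and > 0", call. = FALSE)
  }
  tibble::tibble(whr = wc / hc, whtr = wc / height_cm)
}

#' Visceral Adiposity Index
#'
#' Sex-specific composite of waist circumference, BMI, triglycerides and HDL
#' cholesterol that estimates visceral adipose dysfunction:
#' \deqn{VAI_{male} = \frac{WC}{39.68 + 1.88\,BMI} \cdot \frac{TG}{1.03}
#'   \cdot \frac{1.31}{HDL}}
#' \deqn{VAI_{female} = \frac{WC}{36.58 + 1.89\,BMI} \cdot \frac{TG}{0.81}
#'   \cdot \frac{1.52}{HDL}}
#' with TG and HDL in mmol/L. A healthy subject at reference lipid levels has
#' VAI close to 1.
#'
#' @param sex Character/factor vector, "male" or "female".
#' @param wc Waist circumference, cm.
#' @param bmi BMI, kg/m^2.
#' @param tg Triglycerides.
#' @param hdl HDL cholesterol.
#' @param lipid_units Units of \code{tg}/\code{hdl}: "mmol/L" (default) or
#'   "mg/dL" (converted internally: TG / 88.57, HDL / 38.67).
#' @return Positive VAI values.
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl,
                        lipid_units = c("mmol/L", "mg/dL")) {
  lipid_units <- match.arg(lipid_units)
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(!is.finite(c(wc, bmi, tg, hdl))) || any(c(wc, bmi, tg, hdl) <= 0)) {
    stop("wc, bmi, tg and hdl must be finite and > 0", call. = FALSE)
  }
  if (lipid_units == "mg/dL") {
    tg <- tg / 88.57
    hdl <- hdl / 38.67
  }
  male <- sex == "male"
  denom <- ifelse(male, 39.68 + 1.88 * bmi, 36.58 + 1.89 * bmi)
  tg_ref <- ifelse(male, 1.03, 0.81)
  hdl_ref <- ifelse(male, 1.31, 1.52)
  (wc / denom) * (tg / tg_ref) * (hdl_ref / hdl)
}

#' Derived adiposity measures for one timepoint
#'
#' Convenience wrapper computing BMI, both waist ratios and VAI from a raw
#' anthropometry table.
#'
#' @param records Data frame with columns \code{participant_id}, \code{sex},
#'   \code{weight} (kg), \code{height} (m), \code{wc}, \code{hc} (cm),
#'   \code{tg}, \code{hdl}.
#' @param lipid_units Passed to [compute_vai()].
#' @return Tibble: \code{participant_id}, \code{bmi}, \code{wc}, \code{whr},
#'   \code{whtr}, \code{vai}.
#' @export
derive_measures <- function(records, lipid_units = c("mmol/L", "mg/dL")) {
  lipid_units <- match.arg(lipid_units)
  bmi <- compute_bmi(records$weight, records$height)
  ratios <- compute_waist_ratios(records$wc, records$hc, records$height * 100)
  vai <- compute_vai(records$sex, records$wc, bmi, records$tg, records$hdl,
                     lipid_units = lipid_units)
  tibble::tibble(
    participant_id = records$participant_id,
    bmi = bmi, wc = records$wc,
    whr = ratios$whr, whtr = ratios$whtr, vai = vai
  )
}

#' Changes in adiposity measures between two timepoints
#'
#' Deltas are follow-up minus baseline. Each binary increase flag is 1 iff the
#' corresponding delta is strictly positive; a delta of exactly zero is coded
#' 0 (change <= 0).
#'
#' @param baseline,followup Tibbles as returned by [derive_measures()] for the
#'   same participants.
#' @param ratio Which waist ratio feeds \code{delta_whr} /
#'   \code{increased_whr}: "whr" (waist-to-hip, default) or "whtr"
#'   (waist-to-height).
#' @return Tibble with \code{participant_id}, \code{delta_bmi},
#'   \code{delta_wc}, \code{delta_whr}, \code{delta_vai} and the four
#'   \code{increased_*} flags.
#' @export
compute_changes <- function(baseline, followup, ratio = c("whr", "whtr")) {
  ratio <- match.arg(ratio)
  if (!identical(baseline$participant_id, followup$participant_id)) {
    stop("baseline and follow-up tables must cover the same participants ",
         "in the same order", call. = FALSE)
  }
  d_bmi <- followup$bmi - baseline$bmi
  d_wc <- followup$wc - baseline$wc
  d_whr <- followup[[ratio]] - baseline[[ratio]]
  d_vai <- followup$vai - baseline$vai
  tibble::tibble(
    participant_id = baseline$participant_id,
    delta_bmi = d_bmi, delta_wc = d_wc, delta_whr = d_whr, delta_vai = d_vai,
    increased_bmi = as.integer(d_bmi > 0),
    increased_wc = as.integer(d_wc > 0),
    increased_whr = as.integer(d_whr > 0),
    increased_vai = as.integer(d_vai > 0)
  )
}
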