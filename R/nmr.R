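# Solvent-shift chameleonicity descriptors for exchangeable NH protons:
# delta-delta = d(DMSO) - d(CDCl3) and the derived hydrogen-bond acidity
# A_NMR, with IMHB-strength classification.

# half-up decimal rounding for report columns (full precision kept upstream)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' NH chemical-shift solvent difference
#'
#' `delta_delta = d(DMSO-d6) - d(CDCl3)` in ppm for an exchangeable proton.
#' Large positive values mean the proton is solvent-exposed (DMSO accepts
#' its hydrogen bond); values near zero mean it is shielded by an
#' intramolecular hydrogen bond. Negative values are allowed but unusual.
#'
#' @param delta_dmso_ppm,delta_cdcl3_ppm Chemical shifts (ppm).
#' @return delta-delta in ppm.
#' @export
#' @examples
#' delta_delta(9.00, 8.36)  # 0.64
delta_delta <- function(delta_dmso_ppm, delta_cdcl3_ppm) {
  stopifnot(is.finite(delta_dmso_ppm), is.finite(delta_cdcl3_ppm))
  delta_dmso_ppm - delta_cdcl3_ppm
}

#' Hydrogen-bond acidity descriptor A_NMR
#'
#' Linear calibration from the NH solvent shift difference:
#' `A = intercept + slope * delta_delta`. The default constants
#' (slope 0.133 per ppm, intercept 0.0065) reproduce the published
#' calibration to two decimals across its worked range; the constants used
#' are recorded as attributes of the result.
#'
#' @param delta_delta_ppm Shift difference in ppm.
#' @param slope,intercept Calibration constants.
#' @return A_NMR (dimensionless, full precision; round with
#'   `round_half_up(x, 2)` for reporting). Attributes `slope` and
#'   `intercept` echo the calibration.
#' @export
#' @examples
#' round(a_nmr(0.64), 2)  # 0.09
a_nmr <- function(delta_delta_ppm, slope = 0.133, intercept = 0.0065) {
  stopifnot(is.finite(delta_delta_ppm))
  structure(intercept + slope * delta_delta_ppm,
            slope = slope, intercept = intercept)
}

#' Classify IMHB strength from A_NMR
#'
#' NH protons with `A_NMR < 0.05` indicate strong intramolecular hydrogen
#' bonds; `A_NMR > 0.15` indicates their absence; values between are
#' intermediate.
#'
#' @param a A_NMR value(s).
#' @param strong_max,absent_min Class boundaries (defaults 0.05 and 0.15).
#' @return Character vector in `"strong"`, `"intermediate"`, `"absent"`.
#' @export
classify_imhb_strength <- function(a, strong_max = 0.05, absent_min = 0.15) {
  stopifnot(all(is.finite(a)))
  dplyr::case_when(a < strong_max ~ "strong",
                   a > absent_min ~ "absent",
                   TRUE ~ "intermediate")
}

#' NMR shift table with derived descriptors
#'
#' Takes per-proton shift pairs (repeated rows per proton are replicate
#' measurements and are kept as-is) and appends delta-delta, A_NMR (full
#' precision and 2-decimal report column) and the IMHB strength class.
#'
#' @param shifts Tibble/data frame with columns `proton_label`,
#'   `delta_dmso_ppm`, `delta_cdcl3_ppm`.
#' @param slope,intercept Calibration constants for [a_nmr()].
#' @return Input tibble with columns `delta_delta_ppm`, `a_nmr`,
#'   `a_nmr_2dp`, `imhb_class` appended.
#' @export
nmr_shift_table <- function(shifts, slope = 0.133, intercept = 0.0065) {
  shifts <- as_tibble(shifts)
  need <- c("proton_label", "delta_dmso_ppm", "delta_cdcl3_ppm")
  miss <- setdiff(need, names(shifts))
  if (length(miss) > 0)
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  shifts |>
    mutate(
      delta_delta_ppm = delta_delta(.data$delta_dmso_ppm,
                                    .data$delta_cdcl3_ppm),
      a_nmr = as.numeric(a_nmr(.data$delta_delta_ppm, slope, intercept)),
      a_nmr_2dp = round_half_up(.data$a_nmr, 2),
      imhb_class = classify_imhb_strength(.data$a_nmr_2dp)
    )
}
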