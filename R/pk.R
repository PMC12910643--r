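# Assay-reduction calculators: microsomal intrinsic clearance with liver
# scaling, PAMPA apparent permeability, fold-ratio comparisons, and 4PL
# dose-response fitting with hook-effect handling.

#' Scaled microsomal intrinsic clearance
#'
#' Converts the percent of parent compound remaining after a microsomal
#' incubation into intrinsic clearance scaled to whole-body units:
#' `CLint = ln(100 / percent) / t / C_protein * SF_liver * SF_body`
#' (mL/min/kg), with the default scaling factors 45.4 mg microsomal protein
#' per g liver and 87.5 g liver per kg body weight.
#'
#' With several replicate percentages, `mode = "per_replicate"` computes one
#' CLint per replicate and averages (the convention consistent with
#' replicate-level reporting); `mode = "mean_percent"` averages the
#' percentages first.
#'
#' @param percent_remaining Percent of compound remaining at `time_min`
#'   (one value or replicates), in (0, 100].
#' @param time_min Incubation time in minutes (default 30).
#' @param protein_mg_ml Microsomal protein concentration (mg/mL,
#'   default 0.2).
#' @param protein_per_liver Scaling factor (mg protein / g liver,
#'   default 45.4).
#' @param liver_per_kg Scaling factor (g liver / kg body weight,
#'   default 87.5).
#' @param mode Replicate handling, `"per_replicate"` or `"mean_percent"`.
#' @return CLint in mL/min/kg (full precision; round for reporting).
#' @export
#' @examples
#' round(clint_scaled(6.75))  # 1785
clint_scaled <- function(percent_remaining, time_min = 30,
                         protein_mg_ml = 0.2, protein_per_liver = 45.4,
                         liver_per_kg = 87.5,
                         mode = c("per_replicate", "mean_percent")) {
  mode <- match.arg(mode)
  if (any(!is.finite(percent_remaining)) ||
      any(percent_remaining <= 0) || any(percent_remaining > 100))
    abort("percent_remaining must lie in (0, 100]")
  stopifnot(time_min > 0, protein_mg_ml > 0)
  one <- function(pct)
    log(100 / pct) / time_min / protein_mg_ml *
      protein_per_liver * liver_per_kg
  if (mode == "mean_percent") one(mean(percent_remaining))
  else mean(vapply(percent_remaining, one, numeric(1)))
}

#' PAMPA apparent permeability
#'
#' Two-compartment, equilibrium-corrected apparent permeability from a
#' parallel artificial membrane assay:
#' `P = -(V_D * V_A) / ((V_D + V_A) * A * t) * ln(1 - C_A(t) / C_eq)` with
#' `C_eq = C_D0 * V_D / (V_D + V_A)`. Volumes in mL (= cm^3), area in cm^2,
#' time in hours; the result is in cm/s. Concentrations may be in any
#' common unit; only the ratio enters.
#'
#' @param c_donor0 Initial donor concentration.
#' @param c_acceptor_t Acceptor concentration at `time_h`; must be below
#'   the equilibrium concentration.
#' @param area_cm2 Membrane area (cm^2).
#' @param v_donor_ml,v_acceptor_ml Donor/acceptor volumes (mL; defaults
#'   0.3 and 0.2, the kit values).
#' @param time_h Incubation time (hours, default 4).
#' @return Apparent permeability in cm/s.
#' @export
papp <- function(c_donor0, c_acceptor_t, area_cm2,
                 v_donor_ml = 0.3, v_acceptor_ml = 0.2, time_h = 4) {
  stopifnot(c_donor0 > 0, c_acceptor_t >= 0, area_cm2 > 0,
            v_donor_ml > 0, v_acceptor_ml > 0, time_h > 0)
  c_eq <- c_donor0 * v_donor_ml / (v_donor_ml + v_acceptor_ml)
  if (c_acceptor_t >= c_eq)
    abort("acceptor concentration is at/beyond equilibrium; Papp undefined")
  t_s <- time_h * 3600
  -(v_donor_ml * v_acceptor_ml) /
    ((v_donor_ml + v_acceptor_ml) * area_cm2 * t_s) *
    log(1 - c_acceptor_t / c_eq)
}

#' Fold ratio of two assay values
#'
#' Simple quotient with a declared reporting rounding (e.g. "3.4-fold" at
#' one decimal).
#'
#' @param numerator,denominator Positive values on the same scale.
#' @param digits Optional decimals for the reported ratio (`NA` = full
#'   precision).
#' @return The (optionally rounded) ratio.
#' @export
#' @examples
#' fold_ratio(1.20, 0.348, digits = 1)  # 3.4
fold_ratio <- function(numerator, denominator, digits = NA) {
  if (any(denominator == 0)) abort("zero denominator in fold ratio")
  if (any(denominator < 0)) abort("denominator must be positive")
  r <- numerator / denominator
  if (is.na(digits)) r else round_half_up(r, digits)
}

# 4PL: response = bottom + (top - bottom) / (1 + (c / dc50)^h), h > 0
four_pl <- function(conc, bottom, top, dc50, h) {
  bottom + (top - bottom) / (1 + (conc / dc50)^h)
}

#' Fit a degradation dose-response curve with hook-effect handling
#'
#' Workflow for degrader dose-response data where high concentrations show
#' a hook effect (response rising again as ternary-complex formation is
#' outcompeted):
#' \enumerate{
#'   \item The hook region is detected as the maximal strictly-increasing
#'     suffix of mean responses that starts at the global minimum; it is
#'     empty when responses are monotone non-increasing.
#'   \item A 4-parameter logistic
#'     `response = bottom + (top - bottom) / (1 + (c / DC50)^h)` is fitted
#'     by least squares to all points up to and including the
#'     global-minimum concentration (i.e. excluding the hook region),
#'     giving DC50 and the main Hill coefficient.
#'   \item When the hook region spans at least 3 points (counting the
#'     minimum), an increasing Hill curve is fitted from the minimum
#'     upward, giving the hook Hill coefficient.
#' }
#'
#' @param concentrations_nM Strictly positive, strictly ascending
#'   concentrations (nM); at least 4.
#' @param response_pct Responses as % of vehicle (already normalised).
#' @return An object of class `dose_response_fit` with elements `dc50_nM`,
#'   `hill`, `top`, `bottom`, `fit_window` (indices used by the main fit),
#'   `hook_region` (index suffix after the minimum; `integer(0)` if none),
#'   `hook_hill` (`NA` if not fitted), `data`, `sse`. Methods: `tidy()`,
#'   `glance()`, `autoplot()`, `predict()`.
#' @export
fit_dose_response <- function(concentrations_nM, response_pct) {
  conc <- as.numeric(concentrations_nM); r <- as.numeric(response_pct)
  if (length(conc) < 4) abort("need at least 4 concentrations for the main fit")
  if (length(r) != length(conc)) abort("concentration/response length mismatch")
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    abort("concentrations must be strictly positive and strictly ascending")
  if (any(!is.finite(r))) abort("non-finite responses")
  n <- length(conc)

  m <- max(which(r == min(r)))          # global minimum, last occurrence
  s <- n
  while (s > 1 && r[s - 1] < r[s]) s <- s - 1
  hook_region <- if (s == m && s < n) (m + 1L):n else integer(0)

  window <- seq_len(m)
  if (length(window) < 4)
    abort(sprintf(
      "only %d points before the hook region; need at least 4 for the main fit",
      length(window)))
  main <- fit_4pl(conc[window], r[window])

  hook_hill <- NA_real_
  if (length(hook_region) >= 2 && (length(hook_region) + 1) >= 3)
    hook_hill <- fit_hook_hill(conc[m:n], r[m:n])

  structure(
    list(dc50_nM = main$dc50, hill = main$h, top = main$top,
         bottom = main$bottom, fit_window = window,
         hook_region = hook_region, hook_hill = hook_hill,
         data = tibble(conc_nM = conc, response_pct = r),
         sse = main$sse, converged = main$converged),
    class = "dose_response_fit")
}

# Levenberg-Marquardt 4PL fit from 5 deterministic starts; best SSE wins.
fit_4pl <- function(conc, r) {
  dc_grid <- exp(quantile(log(conc), c(0.2, 0.35, 0.5, 0.65, 0.8),
                          names = FALSE))
  h_grid <- c(0.7, 1, 1.3, 2, 0.5)
  best <- NULL
  for (k in seq_len(5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ bottom + (top - bottom) / (1 + (conc / dc50)^h),
        data = data.frame(conc = conc, r = r),
        start = list(bottom = min(r), top = max(r),
                     dc50 = dc_grid[k], h = h_grid[k]),
        lower = c(bottom = -Inf, top = -Inf, dc50 = min(conc) / 100,
                  h = 0.05),
        upper = c(bottom = Inf, top = Inf, dc50 = max(conc) * 100, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      p <- coef(fit)
      best <- list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                   dc50 = unname(p["dc50"]), h = unname(p["h"]), sse = sse,
                   converged = TRUE)
    }
  }
  if (is.null(best))
    abort("4PL fit failed to converge from all deterministic starts",
          class = "chameleonics_fit_failure")
  if (best$dc50 < min(conc) || best$dc50 > max(conc))
    warn("fitted DC50 lies outside the fitted concentration span")
  best
}

# Increasing Hill fit over the hook region (minimum upward); baseline fixed
# at the minimum response, so 3 points suffice.
fit_hook_hill <- function(conc, r) {
  r0 <- r[1]
  k_grid <- exp(quantile(log(conc), c(0.3, 0.5, 0.7), names = FALSE))
  h_grid <- c(1, 2, 3)
  best <- NULL
  for (k in seq_along(k_grid)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ r0 + amp * conc^h / (conc^h + K^h),
        data = data.frame(conc = conc, r = r),
        start = list(amp = max(r) - r0 + 1e-6, K = k_grid[k], h = h_grid[k]),
        lower = c(amp = 0, K = min(conc) / 100, h = 0.05),
        upper = c(amp = Inf, K = max(conc) * 100, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(h = unname(coef(fit)["h"]), sse = sse)
  }
  if (is.null(best)) NA_real_ else best$h
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> DC50 = %.3g nM, Hill = %.3g, plateaus %.3g/%.3g\n",
              x$dc50_nM, x$hill, x$top, x$bottom))
  if (length(x$hook_region) > 0)
    cat(sprintf("  hook region: top %d concentration(s); hook Hill = %.3g\n",
                length(x$hook_region), x$hook_hill))
  else cat("  no hook region detected\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("dc50_nM", "hill", "top", "bottom", "hook_hill"),
         estimate = c(x$dc50_nM, x$hill, x$top, x$bottom, x$hook_hill))
}

#' @exportS3Method generics::glance
glance.dose_response_fit <- function(x, ...) {
  tibble(dc50_nM = x$dc50_nM, hill = x$hill, top = x$top,
         bottom = x$bottom, n = nrow(x$data),
         n_fit = length(x$fit_window), n_hook = length(x$hook_region),
         hook_hill = x$hook_hill, sse = x$sse)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_nM else newdata$conc_nM
  four_pl(conc, object$bottom, object$top, object$dc50_nM, object$hill)
}
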