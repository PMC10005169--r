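#' Band-averaged hemoglobin extinction coefficients
#'
#' Averages the high-resolution extinction coefficients over each camera
#' band's effective response (filter response times optics transmission and
#' illuminant), giving the 16-vector extinctions used in the multispectral
#' Beer-Lambert regression.
#'
#' @param tab An [load_extinction_table()] result.
#' @param cam A [camera_model()].
#' @return Object of class `band_extinctions`: list with `eps_hbo2_band` and
#'   `eps_hb_band` (length `cam$n_bands`).
#' @export
band_average_extinctions <- function(tab, cam) {
  e <- eps_at(tab, cam$wavelengths)
  structure(
    list(eps_hbo2_band = integrate_bands(e$hbo2, cam),
         eps_hb_band = integrate_bands(e$hb, cam)),
    class = "band_extinctions")
}

#' Beer-Lambert regression of a band reflectance spectrum
#'
#' Converts the reflectance spectrum to absorbance a_k = -log(r_k) and fits
#' the linear model a = eps_HbO2 * (v_HbO2 l) + eps_Hb * (v_Hb l) + g by
#' ordinary least squares, where the intercept g absorbs scattering losses.
#' The oxygenation s = v_HbO2 l / (v_HbO2 l + v_Hb l) and total hemoglobin
#' path product v_HbT l are derived from the coefficients. Estimates are NOT
#' clipped to a plausible range: values such as s > 1 are reported as fitted.
#'
#' The input should be the physical (reference-normalized) reflectance, not
#' an l2-normalized spectrum; a positive rescaling of the reflectance only
#' shifts the intercept, leaving s unchanged.
#'
#' @param spectrum Band reflectance vector, strictly positive.
#' @param bx A [band_average_extinctions()] result.
#' @return Object of class `beer_lambert_fit`: list with `v_hbo2_l`,
#'   `v_hb_l`, `scatter_offset`, `s`, `v_hbt_l`, `residual_norm`.
#' @export
beer_lambert_fit <- function(spectrum, bx) {
  stopifnot(inherits(bx, "band_extinctions"))
  if (any(!is.finite(spectrum)) || any(spectrum <= 0)) {
    stop("Beer-Lambert fit needs strictly positive reflectance in all bands")
  }
  a <- -log(spectrum)
  X <- cbind(hbo2 = bx$eps_hbo2_band, hb = bx$eps_hb_band, offset = 1)
  if (qr(X)$rank < 3) stop("collinear Beer-Lambert design matrix")
  fit <- stats::lm.fit(X, a)
  cf <- fit$coefficients
  v_hbt <- cf[["hbo2"]] + cf[["hb"]]
  structure(
    list(v_hbo2_l = cf[["hbo2"]], v_hb_l = cf[["hb"]],
         scatter_offset = cf[["offset"]],
         s = if (v_hbt != 0) cf[["hbo2"]] / v_hbt else NA_real_,
         v_hbt_l = v_hbt,
         residual_norm = sqrt(sum(fit$residuals^2))),
    class = "beer_lambert_fit")
}

#' Classify perfusion state from Beer-Lambert parameter series
#'
#' Computes the AU-ROC (exactly as [evaluate_auroc()]) once with the fitted
#' oxygenation s and once with the total hemoglobin product v_HbT l as the
#' decision score. Ischemia reduces both parameters, so by default lower
#' values score as more ischemic (`direction = "lower"` negates the
#' parameter before the AU-ROC).
#'
#' @param fits List of `beer_lambert_fit` objects, one per frame.
#' @param states Character or 0/1 vector per frame; "ischemic"/1 is positive.
#' @param direction "lower" (default) if smaller parameter values indicate
#'   ischemia, "higher" otherwise.
#' @return Named vector with elements `auroc_s` and `auroc_vhbt`.
#' @export
classify_by_baseline <- function(fits, states, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  s_vals <- vapply(fits, function(f) f$s, numeric(1))
  v_vals <- vapply(fits, function(f) f$v_hbt_l, numeric(1))
  pos <- states == "ischemic" | states == 1
  sgn <- if (direction == "lower") -1 else 1
  c(auroc_s = evaluate_auroc(sgn * s_vals[!pos], sgn * s_vals[pos]),
    auroc_vhbt = evaluate_auroc(sgn * v_vals[!pos], sgn * v_vals[pos]))
}
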