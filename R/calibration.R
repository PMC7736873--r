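## Conversion-coefficient computation and HMR standardization.
##
## A camera-collimator system is characterized by its conversion coefficient
##   CC = ((HMR_ant + HMR_post)/2 - 1) / ((2.60 + 3.50)/2 - 1),
## the ratio of the measured mean excess HMR to the designated mean excess
## (denominator 2.05). Institutional HMR values are mapped onto the
## medium-energy reference scale through the affine standardization
##   HMR_std = CC_std / CC_i * (HMR_i - 1) + 1,   with CC_std = 0.88.

#' Reference conversion coefficient of the standard (MEGP) scale
#'
#' The standardized conversion coefficient that defines the medium-energy
#' general-purpose reference scale all HMR values are converted to.
#'
#' @return 0.88.
#' @export
cc_std_reference <- function() 0.88

#' Conversion coefficient of a camera-collimator system
#'
#' @param hmr_ant,hmr_post Measured anterior and posterior phantom HMR
#'   (both > 0).
#' @param provenance `"institutional"` or `"multicenter"`.
#' @return An object of class `mibg_cc` with fields `value`, `hmr_ant`,
#'   `hmr_post`, `designated`, `provenance` and a `pathological` flag set
#'   when the value falls outside (0, 1] (no clamping is applied).
#' @examples
#' conversion_coefficient(2.60, 3.50)$value # designated inputs give 1
#' conversion_coefficient(2.00, 2.5871)$value # ~0.631
#' @export
conversion_coefficient <- function(hmr_ant, hmr_post,
                                   provenance = c("institutional", "multicenter")) {
  provenance <- match.arg(provenance)
  if (!(is.numeric(hmr_ant) && length(hmr_ant) == 1L && is.finite(hmr_ant) && hmr_ant > 0) ||
    !(is.numeric(hmr_post) && length(hmr_post) == 1L && is.finite(hmr_post) && hmr_post > 0)) {
    abort("anterior and posterior HMR must be positive finite numbers")
  }
  denom <- mean(DESIGNATED_HMR) - 1 # (2.60 + 3.50)/2 - 1 = 2.05
  value <- ((hmr_ant + hmr_post) / 2 - 1) / denom
  structure(
    list(
      value = value,
      hmr_ant = hmr_ant,
      hmr_post = hmr_post,
      designated = DESIGNATED_HMR,
      provenance = provenance,
      pathological = value <= 0 || value > 1
    ),
    class = "mibg_cc"
  )
}

## Vectorized CC formula for tabular pipelines.
cc_from_hmr <- function(hmr_ant, hmr_post) {
  ((hmr_ant + hmr_post) / 2 - 1) / (mean(DESIGNATED_HMR) - 1)
}

#' @export
print.mibg_cc <- function(x, ...) {
  cat(sprintf(
    "<mibg_cc> CC = %.4f (%s; HMR ant %.3f, post %.3f)%s\n",
    x$value, x$provenance, x$hmr_ant, x$hmr_post,
    if (x$pathological) " [pathological]" else ""
  ))
  invisible(x)
}

#' Tidy a conversion coefficient
#'
#' @param x A `mibg_cc` object.
#' @param ... Unused.
#' @return A one-row tibble with `cc`, `hmr_ant`, `hmr_post`, `provenance`,
#'   `pathological`.
#' @export
tidy.mibg_cc <- function(x, ...) {
  tibble(
    cc = x$value, hmr_ant = x$hmr_ant, hmr_post = x$hmr_post,
    provenance = x$provenance, pathological = x$pathological
  )
}

#' Standardize HMR onto the medium-energy reference scale
#'
#' Applies the affine standardization
#' `HMR_std = cc_std / cc_i * (hmr - 1) + 1`. The map fixes HMR = 1, is
#' strictly increasing in `hmr`, and composes: standardizing A to B and B to
#' the reference equals standardizing A to the reference directly. Values
#' below 1 are preserved, not clamped.
#'
#' @param hmr Measured institutional HMR (vectorized).
#' @param cc_i Institutional conversion coefficient(s), > 0.
#' @param cc_std Reference conversion coefficient (default 0.88).
#' @return Standardized HMR, same length as `hmr`.
#' @examples
#' standardize_hmr(2.0, 0.55) # 0.88/0.55 * 1 + 1 = 2.6
#' @export
standardize_hmr <- function(hmr, cc_i, cc_std = cc_std_reference()) {
  if (!all(is.finite(cc_i)) || any(cc_i <= 0)) abort("`cc_i` must be > 0")
  if (!all(is.finite(cc_std)) || any(cc_std <= 0)) abort("`cc_std` must be > 0")
  cc_std / cc_i * (hmr - 1) + 1
}

#' End-to-end conversion coefficient of a simulated system
#'
#' Simulates anterior and posterior phantom acquisitions through the given
#' collimator and settings, measures both HMRs with the automatic ROI
#' pipeline, and returns the resulting conversion coefficient. With a noisy
#' acquisition, the two views use consecutive seeds derived from
#' `settings$seed`.
#'
#' @param collimator A [collimator_spec()] or [ideal_collimator()].
#' @param settings [acquisition_settings()].
#' @param noise Add Poisson noise?
#' @param penetration_fwhm_mm Passed to [simulate_planar()].
#' @return An object of class `mibg_cc`.
#' @export
end_to_end_cc <- function(collimator, settings = acquisition_settings(),
                          noise = FALSE, penetration_fwhm_mm = 150) {
  one_view <- function(view, seed_offset) {
    s <- settings
    if (!is.null(s$seed)) s$seed <- s$seed + seed_offset
    amap <- build_phantom(s$pixel_size_mm, view)
    img <- simulate_planar(amap, collimator, s,
      noise = noise,
      penetration_fwhm_mm = penetration_fwhm_mm
    )
    measure_hmr(img, view)$hmr
  }
  conversion_coefficient(one_view("anterior", 0L), one_view("posterior", 1L))
}
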