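#' Inverse-square and SOBP off-center corrections
#'
#' The monitor-unit calibration point of a patient beam generally sits away
#' from the isocenter and away from the center of the spread-out Bragg peak
#' (SOBP).  Because commissioning measurements place the detector at the
#' isocenter at the SOBP center, the predicted output must be carried to the
#' calibration point by an inverse-square correction.
#'
#' `isf_ocf()` is the combined inverse-square and SOBP off-center factor used
#' by all three models,
#' \deqn{ISF_{OCF} = \left(\frac{ESAD - \Delta z_p}{ESAD - \Delta z_p - \Delta z}\right)^2,}
#' where `ESAD` is the effective source-to-axis distance (cm), `dz_p` is the
#' signed longitudinal distance of the calibration point from the SOBP center
#' (negative downstream, positive upstream), and `dz` is the signed offset
#' between the SOBP center and the isocenter.  It assumes the calibration
#' point lies on the flat SOBP plateau.
#'
#' `isf()` and `sobp_ocf()` are the two legacy factors that `isf_ocf()`
#' replaces: the plain inverse-square factor `(SAD/SPD)^2` and the SOBP
#' off-center factor `PDD * (SSD + d_p)^2 / (SSD + d_c)^2` for a fixed
#' source-to-detector distance.  They are provided for comparison with the
#' original correction-based formulation and are not used by the default
#' prediction chain.
#'
#' @param ESAD Effective source-to-axis distance (cm), > 0.
#' @param dz_p Signed distance (cm) of the calibration point from the SOBP
#'   center, negative downstream / positive upstream.
#' @param dz Signed offset (cm) between SOBP center and isocenter.
#' @return A numeric factor (dimensionless), vectorized over inputs.
#' @examples
#' isf_ocf(185, dz_p = 0, dz = 5)  # 1.0563
#' isf(200, 190)
#' @export
isf_ocf <- function(ESAD, dz_p = 0, dz = 0) {
  num <- ESAD - dz_p
  den <- ESAD - dz_p - dz
  if (any(ESAD <= 0)) abort("ESAD must be positive")
  if (any(num <= 0) || any(den <= 0)) {
    abort("degenerate geometry: ESAD - dz_p and ESAD - dz_p - dz must be positive")
  }
  (num / den)^2
}

#' @rdname isf_ocf
#' @param SAD Source-to-axis (isocenter) distance (cm), > 0.
#' @param SPD Source-to-calibration-point distance (cm), > 0.
#' @export
isf <- function(SAD, SPD) {
  if (any(SAD <= 0) || any(SPD <= 0)) abort("distances must be positive")
  (SAD / SPD)^2
}

#' @rdname isf_ocf
#' @param pdd Percent depth dose at the point, as a fraction of the dose at
#'   the SOBP center (1.0 on the flat plateau).
#' @param SSD Source-to-surface distance (cm) of the depth-dose scan, > 0.
#' @param d_p Depth (cm) of the calibration point, > 0.
#' @param d_c Depth (cm) of the SOBP center, > 0.
#' @export
sobp_ocf <- function(pdd, SSD, d_p, d_c) {
  if (any(SSD <= 0) || any(d_p <= 0) || any(d_c <= 0)) {
    abort("distances must be positive")
  }
  pdd * (SSD + d_p)^2 / (SSD + d_c)^2
}
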