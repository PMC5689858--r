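#' Predict output (cGy/MU) for one or more beams
#'
#' The central prediction function.  For `model = "A"` (correction-based), the
#' output is the product of the reference output and the commissioned factors,
#' \deqn{\Psi_A = \Psi_o \cdot ROF \cdot SOBPF \cdot RSF \cdot ISF_{OCF} \cdot OCR \cdot FSF \cdot GACF.}
#' For `model = "B"` (analytical) and `model = "C"` (quartic conversion) the
#' first two factors are replaced by a closed-form term in the SOBP shape
#' variable `r` with option-specific constants from [fit_sobp_model()]:
#' \deqn{\Psi_B = CF\,\Psi_o D_c\, \frac{100}{1 + a_0 r^{a_1}} \, (s_0 + s_1 (R - R_L)) \cdot ISF_{OCF} \cdot OCR \cdot FSF \cdot GACF,}
#' \deqn{\Psi_C = (p_0 + p_1 r + p_2 r^2 + p_3 r^3 + p_4 r^4)\,(s_2 + s_3 (R - R_L)) \cdot ISF_{OCF} \cdot OCR \cdot FSF \cdot GACF.}
#'
#' The returned tibble carries one column per factor so every prediction is
#' auditable: the `psi` column equals the product of its breakdown columns
#' (times `psi_o` for model A) to machine precision.  Flag columns mark
#' predictions that used an extrapolated RSF placeholder cell, a small-field
#' override, or a calibration point possibly off the flat SOBP plateau
#' (|dz_p| > M'/2 with M' = 0.81 M, where the inverse-square off-center
#' correction's assumption breaks down).
#'
#' @param beams Data frame of beams (see [validate_beams()] for columns).
#' @param tables A [mu_tables()] object.
#' @param model `"A"`, `"B"` or `"C"`.
#' @param params A `sobp_fit` object from [fit_sobp_model()] (required for
#'   models B and C).
#' @param catalog Option catalog.
#' @param allow_small Permit fields below the smallest measured FSF entry.
#' @param legacy_geometry If `TRUE`, use the legacy SOBPOCF x ISF pair
#'   (columns `pdd`, `SSD`, `d_p`, `d_c`, `SAD`, `SPD` must be present in
#'   `beams`) instead of the combined `ISF_OCF`; off by default.
#' @return The validated beams tibble with factor breakdown columns, `psi`
#'   (cGy/MU) and flag columns appended.
#' @examples
#' tb <- s250_tables()
#' predict_output(beam_spec(13, R = 32, M = 10), tb)
#' @export
predict_output <- function(beams, tables, model = c("A", "B", "C"),
                           params = NULL, catalog = option_catalog(),
                           allow_small = FALSE, legacy_geometry = FALSE) {
  model <- match.arg(model)
  beams <- validate_beams(beams, catalog)
  spec <- catalog[match(beams$option, catalog$option), ]
  geom <- if (legacy_geometry) {
    needed <- c("pdd", "SSD", "d_p", "d_c", "SAD", "SPD")
    if (!all(needed %in% names(beams))) {
      abort(paste0("legacy geometry needs beam columns: ",
                   paste(needed, collapse = ", ")))
    }
    sobp_ocf(beams$pdd, beams$SSD, beams$d_p, beams$d_c) * isf(beams$SAD, beams$SPD)
  } else {
    isf_ocf(spec$ESAD, beams$dz_p, beams$dz)
  }
  ocr <- ocr_factor(tables, beams$option, beams$x, beams$y)
  fsf <- fsf_factor(tables, beams$option, beams$field, catalog, allow_small)
  gacf <- gacf_factor(tables, spec$group, beams$angle)
  out <- beams
  out$flag_off_plateau <- abs(beams$dz_p) > 0.81 * beams$M / 2
  out$flag_small_field <- allow_small &
    field_size(beams$field) < vapply(beams$option, function(o) {
      g <- tables$fsf[tables$fsf$option == o, ]
      if (nrow(g) == 0) -Inf else min(field_size(g$field))
    }, numeric(1))
  if (model == "A") {
    rsf <- rsf_factor(tables, beams$option, beams$R, beams$M, detail = TRUE)
    out$psi_o <- tables$psi_o
    out$rof <- rof_factor(tables, beams$option)
    out$sobpf <- sobpf_factor(tables, beams$option, beams$M)
    out$rsf <- rsf$factor
    out$isf_ocf <- geom
    out$ocr <- ocr
    out$fsf <- fsf
    out$gacf <- gacf
    out$flag_placeholder_rsf <- rsf$placeholder
    out$psi <- out$psi_o * out$rof * out$sobpf * out$rsf *
      out$isf_ocf * out$ocr * out$fsf * out$gacf
  } else {
    if (is.null(params) || !inherits(params, "sobp_fit")) {
      abort("models B and C need a 'sobp_fit' params object; see fit_sobp_model()")
    }
    if (params$model != model) {
      abort(sprintf("params were fitted for model %s, not model %s",
                    params$model, model))
    }
    p <- params$params[match(beams$option, params$params$option), ]
    if (anyNA(p$option)) {
      abort(paste0("no fitted parameters for option(s): ",
                   paste(unique(beams$option[is.na(p$option)]), collapse = ", ")))
    }
    r <- r_index(beams$R, beams$M, params$conv)
    if (any(r < 0)) {
      abort("r < 0: modulation wider than the straggling-corrected range is outside the model domain")
    }
    if (model == "B") {
      out$basic <- p$amp / (1 + p$a0 * r^p$a1)
      out$shift <- p$s0 + p$s1 * (beams$R - spec$R_L)
    } else {
      out$basic <- p$p0 + p$p1 * r + p$p2 * r^2 + p$p3 * r^3 + p$p4 * r^4
      out$shift <- p$s2 + p$s3 * (beams$R - spec$R_L)
    }
    out$r <- r
    out$isf_ocf <- geom
    out$ocr <- ocr
    out$fsf <- fsf
    out$gacf <- gacf
    out$psi <- out$basic * out$shift * out$isf_ocf * out$ocr * out$fsf * out$gacf
  }
  if (any(out$psi <= 0)) abort("non-positive predicted output")
  out
}

#' Convert a planned dose to monitor units
#'
#' MU = D / Psi, where D is the dose (cGy) at the calibration point of the
#' verification plan without compensator and Psi the predicted output
#' (cGy/MU) at that point.  Compensator and patient scatter factors cancel
#' between the plan dose and the output, so they never enter.  The delivered
#' value is additionally rounded to the machine's MU resolution.
#'
#' @param dose Dose (cGy) at the calibration point, > 0.
#' @param psi Predicted output (cGy/MU), > 0.
#' @param resolution Delivery system MU resolution (default 0.1 MU).
#' @return A tibble with `dose`, `psi`, `mu` (unrounded) and `mu_delivered`.
#' @examples
#' dose_to_mu(200, 1.4310)
#' @export
dose_to_mu <- function(dose, psi, resolution = 0.1) {
  if (any(dose <= 0) || any(psi <= 0)) abort("dose and output must be positive")
  mu <- dose / psi
  tibble(dose = dose, psi = psi, mu = mu,
         mu_delivered = round(mu / resolution) * resolution)
}
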