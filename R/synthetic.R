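#' Synthetic ground-truth machine
#'
#' Builds a virtual double-scattered proton machine with a known, smooth
#' ground-truth output function, so that the commissioning pipeline, all
#' three prediction models and the fitting routines can be exercised end to
#' end — and their errors measured against truth — without any physical
#' measurements.
#'
#' The truth output follows the analytical model-B form per option (so model
#' B is well-specified, and models A and C are approximations), with
#' option-specific constants drawn once from documented ranges under the
#' given seed: `a0 ~ U(0.04, 0.09)`, `a1 ~ U(0.55, 0.70)`,
#' `s1 ~ U(0.004, 0.02)` with the convention `s(R_max) = 1`.  Amplitudes are
#' anchored so that each option's output at its reference conditions
#' reproduces the published relative output factor pattern and the reference
#' output 1.06 cGy/MU.  On top of the longitudinal model sit: a smooth
#' asymmetric lateral profile per option (no radial symmetry, mirror
#' differences of a few percent, 1.00 on axis), a sigmoidal field-size curve
#' per group approaching 1 above a 5x5 cm2 equivalent field with a small-field
#' falloff (plus an optional slit-scatter bump for shallow options), and a
#' gantry-angle curve per group with maximum deviations 0.2% (large), 2.3% at
#' 135 degrees (deep) and 3.6% at 150 degrees (small).
#'
#' With `warp > 0` a smooth multiplicative perturbation (amplitude `warp`,
#' recommended <= 0.01) is added so that *no* model is exactly true —
#' useful when studying model comparison rather than recovery.
#'
#' @param catalog Option catalog.
#' @param seed Integer seed for the parameter draws.
#' @param warp Amplitude of the smooth model-misspecification warp (default 0).
#' @param slit_bump Amplitude of the small-field slit-scatter bump added to
#'   the field-size curve of shallow options (default 0).
#' @return An object of class `mu_truth`.
#' @seealso [generate_campaign()], [tables_from_campaign()], [truth_output()]
#' @export
truth_machine <- function(catalog = option_catalog(), seed = 1, warp = 0,
                          slit_bump = 0) {
  set.seed(seed)
  n <- nrow(catalog)
  rof_csv <- read.csv(system.file("extdata", "rof_table.csv", package = "protonmu"))
  rof_ref <- rof_csv$rof[match(catalog$option, rof_csv$option)]
  if (anyNA(rof_ref)) rof_ref[is.na(rof_ref)] <- 1
  par <- tibble(
    option = catalog$option,
    group = catalog$group,
    a0 = runif(n, 0.04, 0.09),
    a1 = runif(n, 0.55, 0.70),
    s1 = runif(n, 0.004, 0.02))
  par$s0 <- 1 - par$s1 * (catalog$R_max - catalog$R_L)
  # lateral profile: gentle asymmetric polynomial, exactly 1 on axis
  par$oc1 <- runif(n, -0.12, 0.12); par$oc2 <- runif(n, -0.12, 0.12)
  par$oc3 <- runif(n, -1.2, 0.3);   par$oc4 <- runif(n, -1.2, 0.3)
  par$oc5 <- runif(n, -0.5, 0.5)
  fsf_par <- tibble(group = c("large", "deep", "small"),
                    beta = runif(3, 0.25, 0.55),
                    mid = runif(3, 3.0, 3.4),
                    width = runif(3, 0.6, 0.9))
  gacf_par <- tibble(group = c("large", "deep", "small"),
                     A = c(0.002, 0.023, 0.036),
                     peak = c(90, 135, 150))
  truth <- structure(list(catalog = catalog, params = par, fsf = fsf_par,
                          gacf = gacf_par, warp = warp, slit_bump = slit_bump,
                          seed = seed),
                     class = "mu_truth")
  # anchor each option's output at its reference conditions to the published
  # relative-output pattern (1.06 cGy/MU for the calibration option), net of
  # the truth field-size factor at the reference field
  r_ref <- r_index(catalog$rof_R, catalog$rof_M)
  fsf_ref <- truth_fsf(truth, catalog$group, catalog$ref_field, catalog$R_max)
  truth$params$amp <- 1.06 * rof_ref * (1 + par$a0 * r_ref^par$a1) / fsf_ref
  truth
}

#' @export
print.mu_truth <- function(x, ...) {
  cat(sprintf("<mu_truth> %d options, seed %d, warp %g\n",
              nrow(x$params), x$seed, x$warp))
  invisible(x)
}

#' Evaluate the ground-truth output
#'
#' @param truth A [truth_machine()] object.
#' @param beams Data frame with columns `option`, `R`, `M` and optionally
#'   `field`, `angle`, `dz_p`, `dz`, `x`, `y` (defaults: reference field,
#'   gantry 0, point at isocenter and SOBP center).
#' @return Numeric vector of true outputs (cGy/MU).
#' @export
truth_output <- function(truth, beams) {
  beams <- as_tibble(beams)
  cat_i <- match(beams$option, truth$catalog$option)
  if (anyNA(cat_i)) abort("beam option not in the truth machine's catalog")
  spec <- truth$catalog[cat_i, ]
  p <- truth$params[match(beams$option, truth$params$option), ]
  for (nm in c("angle", "dz_p", "dz", "x", "y")) {
    if (is.null(beams[[nm]])) beams[[nm]] <- 0
  }
  if (is.null(beams[["field"]])) beams$field <- spec$ref_field
  r <- r_index(beams$R, beams$M)
  psi <- p$amp / (1 + p$a0 * r^p$a1) *
    (p$s0 + p$s1 * (beams$R - spec$R_L)) *
    isf_ocf(spec$ESAD, beams$dz_p, beams$dz) *
    truth_ocr(truth, beams$option, beams$x, beams$y) *
    truth_fsf(truth, spec$group, beams$field, spec$R_max) *
    truth_gacf(truth, spec$group, beams$angle)
  if (truth$warp > 0) {
    psi <- psi * (1 + truth$warp * sin(2 * pi * beams$R / 7.3) *
                    cos(2 * pi * beams$M / 9.1))
  }
  psi
}

#' @noRd
truth_ocr <- function(truth, option, x, y) {
  p <- truth$params[match(option, truth$params$option), ]
  1 + (p$oc1 * x + p$oc2 * y) / 100 +
    (p$oc3 * x^2 + p$oc4 * y^2 + p$oc5 * x * y) / 1e4
}

#' @noRd
truth_fsf <- function(truth, group, field, R_max) {
  fp <- truth$fsf[match(group, truth$fsf$group), ]
  s <- field_size(field)
  f <- 1 - fp$beta / (1 + exp((s - fp$mid) / fp$width))
  if (truth$slit_bump > 0) {
    f <- f + truth$slit_bump * exp(-(s - 3)^2 / 2) * (R_max < 8)
  }
  f
}

#' @noRd
truth_gacf <- function(truth, group, angle) {
  gp <- truth$gacf[match(group, truth$gacf$group), ]
  u <- arc_position(angle) - 5  # 0 at gantry 0, the calibration angle
  1 - gp$A * sin(pi * u / (2 * gp$peak))^2
}

#' Generate a full synthetic measurement campaign
#'
#' Emits every measurement of the commissioning and validation campaign from
#' the ground truth plus multiplicative Gaussian noise
#' `psi = truth * (1 + sigma * eps)`.  The default design reproduces the
#' campaign sizes of the system's commissioning: 24 ROF (each option at its
#' deepest range and reference modulation), 182 SOBPF (per-option modulation
#' sweeps at fixed largest range over `{2, 3, 4, 6, ...}` g/cm2 up to the
#' option maximum), 324 RSF (three ranges — minimum, median, maximum — per
#' option with modulation columns at roughly 3 g/cm2 spacing; grid corners
#' with M > R are not deliverable and therefore not measured), 54 FSF (three
#' options per group, six field sizes), 75 GACF (five options, every 15
#' degrees along the arc) and 272 validation points (random clinical-like
#' (R, M) draws with M >= 3 g/cm2, of which 60 are moved off the SOBP center
#' and/or off isocenter).  A lateral-profile (OCR) block at 10 mm detector
#' spacing is emitted per option in addition.
#'
#' @param truth A [truth_machine()] object.
#' @param sigma Relative measurement noise (default 0.005 = 0.5%).
#' @param seed Integer seed for noise and validation-point draws.
#' @return A tibble of measurement records: `campaign`, beam columns and
#'   `psi` (measured output, cGy/MU).  Deterministic given `truth`, `sigma`
#'   and `seed`.
#' @export
generate_campaign <- function(truth, sigma = 0.005, seed = 1) {
  if (sigma < 0) abort("sigma must be non-negative")
  set.seed(seed)
  catalog <- truth$catalog
  des <- list(
    rof = dplyr::transmute(catalog, campaign = "ROF", option = .data$option,
                           R = .data$rof_R, M = .data$rof_M),
    sobpf = campaign_sobpf(catalog),
    rsf = campaign_rsf(catalog),
    fsf = campaign_fsf(catalog),
    gacf = campaign_gacf(catalog),
    ocr = campaign_ocr(catalog),
    val = campaign_validation(catalog))
  rec <- dplyr::bind_rows(des)
  for (nm in c("angle", "dz_p", "dz", "x", "y")) {
    if (is.null(rec[[nm]])) rec[[nm]] <- 0
    rec[[nm]][is.na(rec[[nm]])] <- 0
  }
  rec$field[is.na(rec$field)] <-
    catalog$ref_field[match(rec$option[is.na(rec$field)], catalog$option)]
  rec$psi <- truth_output(truth, rec) * (1 + sigma * rnorm(nrow(rec)))
  as_tibble(rec)
}

#' @noRd
sobpf_m_grid <- function(M_max) {
  g <- c(2, 3, seq(4, 2 * floor(M_max / 2), by = 2))
  # the sweep always reaches the option maximum; a trailing even point within
  # 0.8 g/cm2 of a fractional maximum is dropped as a near-duplicate
  gap <- M_max - max(g)
  if (gap > 0 && gap < 0.8) g <- g[-length(g)]
  if (M_max > max(g)) g <- c(g, M_max)
  g
}

#' @noRd
campaign_sobpf <- function(catalog) {
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    tibble(campaign = "SOBPF", option = catalog$option[i],
           R = catalog$R_max[i], M = sobpf_m_grid(catalog$M_max[i]))
  })
}

#' @noRd
rsf_m_grid <- function(option, M_max) {
  g <- c(seq(2, M_max, by = 3), M_max)
  # shallow options get an extra low column so every range row keeps >= 3
  # deliverable widths for the placeholder log fit
  if (option %in% c(9, 10, 11, 12, 23, 24)) g <- c(g, 3.5)
  g <- sort(unique(round(g, 1)))
  if (option %in% c(9, 10, 23)) g <- setdiff(g, 8)
  if (option == 22) g <- setdiff(g, 11)
  g
}

#' @noRd
rsf_r_grid <- function(R_min, R_max) {
  c(R_min, round((R_min + R_max) / 2, 1), R_max)
}

#' @noRd
campaign_rsf <- function(catalog) {
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    Ms <- rsf_m_grid(catalog$option[i], catalog$M_max[i])
    Rs <- rsf_r_grid(catalog$R_min[i], catalog$R_max[i])
    g <- expand.grid(R = Rs, M = Ms, KEEP.OUT.ATTRS = FALSE)
    g <- g[g$M <= g$R + 1e-9, ]  # M > R is not deliverable
    tibble(campaign = "RSF", option = catalog$option[i], R = g$R, M = g$M)
  })
}

#' @noRd
campaign_fsf <- function(catalog) {
  opts <- c(1, 6, 12, 13, 15, 17, 18, 20, 24)
  opts <- opts[opts %in% catalog$option]
  fields <- c("circ3.5", "5x5", "10x10", "circ14", "20x20", "circ25")
  purrr::map_dfr(opts, function(o) {
    i <- match(o, catalog$option)
    tibble(campaign = "FSF", option = o, R = catalog$R_max[i],
           M = catalog$rof_M[i], field = fields)
  })
}

#' @noRd
campaign_gacf <- function(catalog) {
  opts <- c(3, 5, 17, 18, 20)
  opts <- opts[opts %in% catalog$option]
  angles <- c(355, seq(0, 180, by = 15), 185)
  purrr::map_dfr(opts, function(o) {
    i <- match(o, catalog$option)
    tibble(campaign = "GACF", option = o, R = catalog$rof_R[i],
           M = catalog$rof_M[i], angle = angles)
  })
}

#' @noRd
campaign_ocr <- function(catalog) {
  purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    half <- if (catalog$applicator[i] == "large") 12 else 7
    ax <- seq(-half, half, by = 1)  # 10 mm detector spacing
    g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
    tibble(campaign = "OCR", option = catalog$option[i],
           R = catalog$rof_R[i], M = catalog$rof_M[i], x = g$x, y = g$y)
  })
}

#' @noRd
campaign_validation <- function(catalog, n_total = 272, n_off = 60) {
  n_opt <- nrow(catalog)
  counts <- rep(n_total %/% n_opt, n_opt)
  extra <- n_total - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  rows <- purrr::map_dfr(seq_len(n_opt), function(i) {
    Rv <- sample(seq(catalog$R_min[i], catalog$R_max[i], by = 0.1), counts[i],
                 replace = TRUE)
    Mv <- vapply(Rv, function(R) {
      sample(seq(3, min(catalog$M_max[i], R), by = 0.1), 1)
    }, numeric(1))
    tibble(campaign = "validation", option = catalog$option[i],
           R = round(Rv, 1), M = round(Mv, 1))
  })
  rows$dz_p <- 0; rows$dz <- 0; rows$x <- 0; rows$y <- 0
  off <- sample(nrow(rows), n_off)
  rows$dz_p[off] <- round(runif(n_off, -5, 5), 1)
  rows$dz[off] <- round(runif(n_off, -2, 2), 1)
  lat <- off[seq_len(n_off %/% 2)]
  rows$x[lat] <- round(runif(length(lat), -5, 5), 1)
  rows$y[lat] <- round(runif(length(lat), -5, 5), 1)
  rows
}

#' Build commissioning tables from a measurement campaign
#'
#' Converts absolute campaign measurements into the relative factor tables of
#' the correction-based model, exactly as each factor is defined: ROF as the
#' ratio of each option's reference-condition output to the calibration
#' option's; SOBPF as the ratio to the option's ROF-modulation output along
#' the fixed-range sweep; RSF as the ratio to the largest-range row at equal
#' modulation (non-deliverable grid corners are then filled by
#' [fill_rsf_placeholders()]); OCR normalized to the central-axis pixel; FSF
#' as the ratio to the group reference field; GACF as the per-group mean
#' ratio to the gantry-0 output.
#'
#' @param records Campaign tibble from [generate_campaign()] (or real
#'   measurements in the same layout).
#' @param catalog Option catalog.
#' @return A [mu_tables()] object.
#' @export
tables_from_campaign <- function(records, catalog = option_catalog()) {
  rec <- as_tibble(records)
  need <- function(tag) {
    d <- rec[rec$campaign == tag, ]
    if (nrow(d) == 0) abort(paste0("campaign is missing the ", tag, " block"))
    d
  }
  rof_d <- need("ROF"); sob_d <- need("SOBPF"); rsf_d <- need("RSF")
  fsf_d <- need("FSF"); gac_d <- need("GACF"); ocr_d <- need("OCR")
  ref_opt <- 20
  psi_ref <- rof_d$psi[rof_d$option == ref_opt]
  if (length(psi_ref) != 1) abort("ROF block lacks the calibration option (20)")
  rof <- tibble(option = rof_d$option, factor = rof_d$psi / psi_ref)

  sobpf <- purrr::map_dfr(unique(sob_d$option), function(o) {
    d <- sob_d[sob_d$option == o, ]
    m_ref <- catalog$rof_M[catalog$option == o]
    denom <- d$psi[abs(d$M - m_ref) < 1e-9]
    if (length(denom) != 1) {
      abort(paste0("SOBPF sweep for option ", o,
                   " lacks the reference modulation ", m_ref))
    }
    tibble(option = o, M = d$M, factor = d$psi / denom)
  })

  rsf <- purrr::map_dfr(unique(rsf_d$option), function(o) {
    d <- rsf_d[rsf_d$option == o, ]
    Rmax <- max(d$R)
    top <- d[abs(d$R - Rmax) < 1e-9, ]
    grid <- expand.grid(R = sort(unique(d$R)), M = sort(unique(d$M)),
                        KEEP.OUT.ATTRS = FALSE)
    i <- match(paste(round(grid$R, 6), round(grid$M, 6)),
               paste(round(d$R, 6), round(d$M, 6)))
    denom <- top$psi[match(round(grid$M, 6), round(top$M, 6))]
    if (anyNA(denom)) {
      abort(paste0("RSF grid for option ", o,
                   " lacks largest-range measurements at some modulation"))
    }
    tibble(option = o, R = grid$R, M = grid$M,
           factor = d$psi[i] / denom,
           placeholder = is.na(i))
  })

  ocr <- purrr::map_dfr(unique(ocr_d$option), function(o) {
    d <- ocr_d[ocr_d$option == o, ]
    c0 <- d$psi[d$x == 0 & d$y == 0]
    if (length(c0) != 1) abort(paste0("OCR grid for option ", o, " lacks the central axis"))
    tibble(option = o, x = d$x, y = d$y, factor = d$psi / c0)
  })

  fsf <- purrr::map_dfr(unique(fsf_d$option), function(o) {
    d <- fsf_d[fsf_d$option == o, ]
    ref_field <- catalog$ref_field[catalog$option == o]
    denom <- d$psi[d$field == ref_field]
    if (length(denom) != 1) {
      abort(paste0("FSF block for option ", o, " lacks the reference field ", ref_field))
    }
    tibble(option = o, field = d$field, factor = d$psi / denom)
  })

  gac_d$group <- catalog$group[match(gac_d$option, catalog$option)]
  gacf <- gac_d |>
    dplyr::group_by(.data$option) |>
    dplyr::mutate(ratio = .data$psi / .data$psi[.data$angle == 0]) |>
    dplyr::group_by(.data$group, .data$angle) |>
    dplyr::summarise(factor = mean(.data$ratio), .groups = "drop")

  tb <- mu_tables(psi_o = psi_ref, rof = rof, sobpf = sobpf, rsf = rsf,
                  ocr = ocr, fsf = fsf, gacf = gacf)
  fill_rsf_placeholders(tb)
}
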