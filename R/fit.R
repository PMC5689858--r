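#' SOBP shape variable r
#'
#' The analytical models are driven by the dimensionless variable
#' `r = (R' - M')/M'`: the ratio of the un-modulated depth to the modulated
#' depth of the spread-out Bragg peak, expressed at the distal/proximal 100%
#' dose points including range straggling.  The vendor reports `R` at the
#' distal 90% dose and `M` from distal 90% to proximal 95%, so the machine
#' values are first converted with `R' = R - delta_R` and `M' = rho_M * M`.
#' The conversion constants are means over a large set of measured SOBP
#' scans for this system and default to `delta_R = 0.31` g/cm2 and
#' `rho_M = 0.81`; both are configurable for other machines.
#'
#' @param R Range (g/cm2), distal 90% dose depth.
#' @param M Modulation width (g/cm2), distal 90% to proximal 95%.
#' @param conv An [r_conversion()] list.
#' @return `r_index()`: the dimensionless r value(s).
#' @examples
#' r_index(15, 10)  # (14.69 - 8.1) / 8.1
#' @export
r_index <- function(R, M, conv = r_conversion()) {
  if (any(M <= 0)) abort("modulation width must be positive")
  if (any(R - conv$delta_R < 0)) abort("R - delta_R must be non-negative")
  ((R - conv$delta_R) - conv$rho_M * M) / (conv$rho_M * M)
}

#' @rdname r_index
#' @param delta_R Mean difference R - R' (g/cm2), > 0.
#' @param rho_M Mean ratio M'/M, > 0.
#' @export
r_conversion <- function(delta_R = 0.31, rho_M = 0.81) {
  stopifnot(delta_R > 0, rho_M > 0)
  list(delta_R = delta_R, rho_M = rho_M)
}

#' Fit the analytical output models (B and C)
#'
#' Two-stage fit of the option-specific constants from absolute output
#' measurements at reference geometry.
#'
#' **Stage 1 (basic term).**  The modulation sweep at each option's largest
#' range (the same dataset used for the SOBP factor, as absolute outputs) is
#' fitted in `r`: for model B, `amp / (1 + a0 * r^a1)` by nonlinear least
#' squares (Levenberg-Marquardt, initialized at `a0 = 0.1, a1 = 0.6` with
#' five restarts on a log grid of `a0`); for model C, a quartic polynomial in
#' `r` by linear least squares.  Both stages minimize *relative* residuals
#' (weights `1/psi^2`), matching the percent-difference metric by which the
#' models are judged.  A sweep with no measurable output variation
#' degenerates to the `a0 = 0` branch and is flagged.
#'
#' **Stage 2 (source-shift term).**  The output change with range inside an
#' option (the effective source moves as absorber thickness changes) is a
#' linear factor `s0 + s1 * (R - R_L)`.  It is fitted on the ratio of
#' measured outputs at the commissioned ranges (minimum, median, maximum) to
#' the stage-1 basic term, selecting at each range the measurement whose `r`
#' is closest to a common target (matched-`r` selection, so stage-1 model
#' error cancels in the ratio).  The convention `s0 + s1 * (R_max - R_L) = 1`
#' holds implicitly because stage 1 absorbs the absolute scale at `R_max`.
#'
#' @param measurements Tibble with columns `option`, `R`, `M`, `psi`
#'   (absolute outputs, cGy/MU, at reference geometry).  Pass e.g. the SOBPF
#'   plus RSF campaigns of [generate_campaign()].
#' @param model `"B"` or `"C"`.
#' @param catalog Option catalog (for `R_L`).
#' @param conv An [r_conversion()] list.
#' @return An object of class `sobp_fit` with elements `model`, `params` (a
#'   tibble of per-option constants and diagnostics), `conv` and `data`.
#'   Methods: [tidy()], [glance()], `print()`, [autoplot()]; use with
#'   [predict_output()].
#' @examples
#' truth <- truth_machine(seed = 1)
#' camp <- generate_campaign(truth, sigma = 0, seed = 1)
#' fit <- fit_sobp_model(dplyr::filter(camp, campaign %in% c("SOBPF", "RSF")),
#'                       model = "B")
#' glance(fit)
#' @export
fit_sobp_model <- function(measurements, model = c("B", "C"),
                           catalog = option_catalog(), conv = r_conversion()) {
  model <- match.arg(model)
  m <- as_tibble(measurements)
  stopifnot(all(c("option", "R", "M", "psi") %in% names(m)))
  if (any(m$psi <= 0)) abort("measured outputs must be positive")
  rows <- lapply(sort(unique(m$option)), function(o) {
    d <- m[m$option == o, ]
    R_L <- catalog$R_L[catalog$option == o]
    if (length(R_L) != 1) abort(paste0("option ", o, " not in catalog"))
    Rmax <- max(d$R)
    sweep <- d[abs(d$R - Rmax) < 1e-9, ]
    sweep <- sweep[!duplicated(sweep$M), ]
    r_sw <- r_index(sweep$R, sweep$M, conv)
    base <- if (model == "B") {
      fit_basic_B(r_sw, sweep$psi, o)
    } else {
      fit_basic_C(r_sw, sweep$psi, o)
    }
    shift <- fit_shift(d, base$fun, R_L, conv, o)
    c(list(option = o, R_L = R_L, n_basic = nrow(sweep)), base$par,
      shift, list(rel_rss = base$rel_rss, degenerate = base$degenerate))
  })
  params <- dplyr::bind_rows(lapply(rows, as_tibble))
  if (model == "B") {
    names(params)[names(params) == "b0"] <- "s0"
    names(params)[names(params) == "b1"] <- "s1"
  } else {
    names(params)[names(params) == "b0"] <- "s2"
    names(params)[names(params) == "b1"] <- "s3"
  }
  structure(list(model = model, params = params, conv = conv, data = m),
            class = "sobp_fit")
}

#' @noRd
fit_basic_B <- function(r, psi, option) {
  if (length(r) < 4) {
    abort(sprintf("option %s: %d modulation points; need >= 4 for model B",
                  option, length(r)))
  }
  if (sd(psi) / mean(psi) < 1e-10) {
    amp <- mean(psi)
    return(list(par = list(amp = amp, a0 = 0, a1 = 1),
                fun = function(rr) rep(amp, length(rr)),
                rel_rss = 0, degenerate = TRUE))
  }
  starts <- c(0.1, 0.01, 0.03, 0.3, 1)  # documented log-grid restarts
  best <- NULL
  dat <- data.frame(r = r, psi = psi)
  for (a0s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        psi ~ A / (1 + a0 * r^a1), data = dat,
        start = list(A = max(psi) * (1 + a0s * min(r)^0.6), a0 = a0s, a1 = 0.6),
        lower = c(A = 0, a0 = 0, a1 = 1e-6),
        weights = 1 / psi^2,
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(((fitted(fit) - psi) / psi)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort(sprintf("option %s: model-B basic-term fit failed to converge after restarts",
                  option))
  }
  cf <- coef(best$fit)
  list(par = list(amp = unname(cf["A"]), a0 = unname(cf["a0"]),
                  a1 = unname(cf["a1"])),
       fun = function(rr) cf["A"] / (1 + cf["a0"] * rr^cf["a1"]),
       rel_rss = sqrt(best$rss / length(r)), degenerate = FALSE)
}

#' @noRd
fit_basic_C <- function(r, psi, option) {
  if (length(unique(round(r, 12))) < 5) {
    abort(sprintf(
      "option %s: %d distinct r values; the quartic needs >= 5 (rank-deficient design)",
      option, length(unique(round(r, 12)))))
  }
  X <- cbind(1, r, r^2, r^3, r^4)
  fit <- lm.wfit(X, psi, w = 1 / psi^2)
  if (fit$rank < 5) {
    abort(sprintf("option %s: rank-deficient quartic design", option))
  }
  cf <- fit$coefficients
  pred <- drop(X %*% cf)
  list(par = list(p0 = cf[[1]], p1 = cf[[2]], p2 = cf[[3]], p3 = cf[[4]],
                  p4 = cf[[5]]),
       fun = function(rr) cf[[1]] + cf[[2]] * rr + cf[[3]] * rr^2 +
         cf[[4]] * rr^3 + cf[[5]] * rr^4,
       rel_rss = sqrt(mean(((pred - psi) / psi)^2)), degenerate = FALSE)
}

#' @noRd
fit_shift <- function(d, basic_fun, R_L, conv, option) {
  Rs <- sort(unique(round(d$R, 9)))
  if (length(Rs) < 3) {
    abort(sprintf("option %s: %d distinct ranges; need >= 3 for the source-shift term",
                  option, length(Rs)))
  }
  r_all <- r_index(d$R, d$M, conv)
  target <- stats::median(r_all[d$R == min(d$R)])
  pick <- vapply(Rs, function(Rv) {
    cand <- which(abs(d$R - Rv) < 1e-9)
    cand[which.min(abs(r_all[cand] - target))]
  }, integer(1))
  rho <- d$psi[pick] / basic_fun(r_all[pick])
  fit <- lm(rho ~ I(d$R[pick] - R_L))
  list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
       n_shift = length(Rs))
}

#' @export
print.sobp_fit <- function(x, ...) {
  cat(sprintf("<sobp_fit> model %s: %d options, r-conversion (delta_R = %g, rho_M = %g)\n",
              x$model, nrow(x$params), x$conv$delta_R, x$conv$rho_M))
  cat(sprintf("  max relative residual norm: %.3g\n", max(x$params$rel_rss)))
  invisible(x)
}

#' @rdname fit_sobp_model
#' @param x A `sobp_fit` object.
#' @param ... Unused.
#' @export
tidy.sobp_fit <- function(x, ...) {
  x$params |>
    tidyr::pivot_longer(-c("option", "n_basic", "n_shift", "degenerate"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select("option", "term", "estimate")
}

#' @rdname fit_sobp_model
#' @export
glance.sobp_fit <- function(x, ...) {
  tibble(model = x$model, n_options = nrow(x$params),
         n_points = nrow(x$data),
         max_rel_rss = max(x$params$rel_rss),
         n_degenerate = sum(x$params$degenerate))
}

#' @rdname fit_sobp_model
#' @param object A `sobp_fit` object.
#' @export
autoplot.sobp_fit <- function(object, ...) {
  d <- object$data |>
    dplyr::group_by(.data$option) |>
    dplyr::filter(abs(.data$R - max(.data$R)) < 1e-9) |>
    dplyr::ungroup() |>
    dplyr::mutate(r = r_index(.data$R, .data$M, object$conv))
  p <- object$params
  curves <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    dd <- d[d$option == p$option[i], ]
    rr <- seq(min(dd$r), max(dd$r), length.out = 100)
    fit <- if (object$model == "B") {
      p$amp[i] / (1 + p$a0[i] * rr^p$a1[i])
    } else {
      p$p0[i] + p$p1[i] * rr + p$p2[i] * rr^2 + p$p3[i] * rr^3 + p$p4[i] * rr^4
    }
    tibble(option = p$option[i], r = rr, psi = fit)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$psi)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = curves, color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$option), scales = "free") +
    ggplot2::labs(x = "r = (R' - M') / M'", y = "output (cGy/MU)",
                  title = paste("Model", object$model, "basic-term fit"))
}
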