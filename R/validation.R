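#' Percent difference between prediction and measurement
#'
#' `(P - M) / M * 100`, the comparison metric used throughout: positive when
#' the model over-predicts the measured output.
#'
#' @param predicted Predicted output(s), cGy/MU.
#' @param measured Measured output(s), cGy/MU, > 0.
#' @return Percent differences.
#' @examples
#' percent_diff(1.02, 1.00)
#' @export
percent_diff <- function(predicted, measured) {
  if (any(measured <= 0)) abort("measured output must be positive")
  (predicted - measured) / measured * 100
}

#' Predict every validation point with each model
#'
#' Convenience wrapper: runs [predict_output()] for model A (from tables) and
#' for any fitted analytical models, against a set of measured validation
#' records, and returns one row per (record, model) with the percent
#' difference.
#'
#' @param records Validation measurement records (tibble with beam columns
#'   and `psi`), e.g. the `validation` campaign of [generate_campaign()].
#' @param tables A [mu_tables()] object (model A); `NULL` to skip model A.
#' @param fits A list of `sobp_fit` objects (models B/C), possibly empty.
#' @param catalog Option catalog.
#' @return Tibble with the beam columns, `model`, `psi_meas`, `psi_pred`,
#'   `pct_diff`.
#' @export
validate_models <- function(records, tables = NULL, fits = list(),
                            catalog = option_catalog()) {
  rec <- as_tibble(records)
  stopifnot("psi" %in% names(rec))
  beams <- rec[setdiff(names(rec), c("psi", "campaign"))]
  out <- list()
  if (!is.null(tables)) {
    pa <- predict_output(beams, tables, model = "A", catalog = catalog)
    out$A <- dplyr::mutate(beams, model = "A", psi_meas = rec$psi,
                           psi_pred = pa$psi)
  }
  if (length(fits) > 0 && is.null(tables)) {
    abort("analytical models still need tables for the OCR/FSF/GACF factors")
  }
  for (f in fits) {
    pf <- predict_output(beams, tables, model = f$model, params = f,
                         catalog = catalog)
    out[[f$model]] <- dplyr::mutate(beams, model = f$model,
                                    psi_meas = rec$psi, psi_pred = pf$psi)
  }
  if (length(out) == 0) abort("nothing to validate: supply tables and/or fits")
  dplyr::bind_rows(out) |>
    dplyr::mutate(pct_diff = percent_diff(.data$psi_pred, .data$psi_meas))
}

#' Summarize validation percent differences
#'
#' Per-model mean, sample standard deviation (n - 1 denominator), extrema,
#' a binned histogram, and a pass/fail verdict against a clinical tolerance
#' (default: all points within +/- 3%).
#'
#' @param diffs Either a numeric vector of percent differences, or a tibble
#'   with columns `pct_diff` and (optionally) `model`.
#' @param tolerance Clinical acceptance bound on |percent difference|.
#' @param bin_width Histogram bin width in percent.
#' @return An object of class `mu_validation`; see [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' summarize_validation(c(-1, 0, 1))
#' @export
summarize_validation <- function(diffs, tolerance = 3, bin_width = 0.5) {
  if (is.numeric(diffs)) diffs <- tibble(model = "A", pct_diff = diffs)
  diffs <- as_tibble(diffs)
  if (is.null(diffs$model)) diffs$model <- "A"
  if (nrow(diffs) == 0) abort("no validation records")
  stats <- diffs |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$pct_diff),
                     sd = sd(.data$pct_diff),
                     min = min(.data$pct_diff),
                     max = max(.data$pct_diff),
                     frac_within = mean(abs(.data$pct_diff) <= tolerance),
                     pass = all(abs(.data$pct_diff) <= tolerance),
                     .groups = "drop")
  if (any(stats$n < 2)) abort("need at least 2 records per model")
  lo <- floor(min(diffs$pct_diff) / bin_width) * bin_width
  hi <- ceiling(max(diffs$pct_diff) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  hist <- diffs |>
    dplyr::group_by(.data$model) |>
    dplyr::reframe(bin_mid = edges[-length(edges)] + bin_width / 2,
                   count = as.vector(table(cut(.data$pct_diff, edges,
                                               include.lowest = TRUE))))
  structure(list(stats = stats, hist = hist, diffs = diffs,
                 tolerance = tolerance, bin_width = bin_width),
            class = "mu_validation")
}

#' @export
print.mu_validation <- function(x, ...) {
  cat(sprintf("<mu_validation> %d records, tolerance +/- %g%%\n",
              nrow(x$diffs), x$tolerance))
  df <- as.data.frame(x$stats)
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname summarize_validation
#' @param x,object A `mu_validation` object.
#' @param ... Unused.
#' @export
tidy.mu_validation <- function(x, ...) x$stats

#' @rdname summarize_validation
#' @export
glance.mu_validation <- function(x, ...) {
  tibble(n = nrow(x$diffs), n_models = nrow(x$stats),
         tolerance = x$tolerance, all_pass = all(x$stats$pass))
}

#' @rdname summarize_validation
#' @export
autoplot.mu_validation <- function(object, ...) {
  ggplot2::ggplot(object$diffs, ggplot2::aes(x = .data$pct_diff)) +
    ggplot2::geom_histogram(binwidth = object$bin_width,
                            fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$tolerance,
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "percent difference (prediction - measurement)",
                  y = "count")
}

#' Compare two models' validation differences with a t-test
#'
#' The three models are evaluated on the same validation points, so the
#' default is a two-sided *paired* t-test of the per-point percent
#' differences; an unpaired two-sample test with pooled variance is available
#' with `paired = FALSE`.
#'
#' @param diffs_x,diffs_y Percent-difference vectors for the two models
#'   (equal length in paired mode).
#' @param paired Use the paired test (default).
#' @return One-row tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
compare_models <- function(diffs_x, diffs_y, paired = TRUE) {
  if (paired && length(diffs_x) != length(diffs_y)) {
    abort("paired comparison needs equal-length difference vectors")
  }
  method <- if (paired) "Paired t-test" else "Two Sample t-test"
  df <- if (paired) length(diffs_x) - 1 else length(diffs_x) + length(diffs_y) - 2
  ht <- tryCatch(
    t.test(diffs_x, diffs_y, paired = paired, var.equal = !paired),
    error = function(e) {
      # degenerate zero-variance data: t is 0/0 (p = 1) or +/-Inf (p = 0)
      delta <- mean(diffs_x) - mean(diffs_y)
      list(method = method,
           statistic = c(t = if (delta == 0) 0 else sign(delta) * Inf),
           parameter = c(df = df),
           p.value = if (delta == 0) 1 else 0)
    })
  if (is.nan(ht$p.value)) {
    # zero-variance differences: t is 0/0, the samples are indistinguishable
    ht$statistic[] <- 0; ht$p.value <- 1
  }
  tibble(method = ht$method, statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value)
}

#' Uncertainty budget by quadrature error propagation
#'
#' Combines independent relative uncertainty components (percent, 1 SD) into
#' a total by quadrature, `total = sqrt(sum(c_i^2))`.
#'
#' `uncertainty_budget()` returns the estimated per-factor component sets for
#' this system: for the correction-based model ROF 0.5, SOBPF 0.5, RSF 1.0,
#' ISF_OCF 0.5, OCR 1.0, GACF 0.5 and FSF 1.0 for large fields (> 5x5 cm2)
#' or 3.0 for small fields; for the analytical models the first three are
#' replaced by a combined basic-plus-source-shift component of 1.5.
#'
#' @param components Named non-negative numeric vector of percent
#'   uncertainties.
#' @return `propagate_uncertainty()`: an object of class `mu_uncertainty`
#'   with elements `components` and `total`.
#' @examples
#' propagate_uncertainty(uncertainty_budget("correction", "large"))$total  # 2.0
#' @export
propagate_uncertainty <- function(components) {
  if (length(components) == 0) abort("no components")
  if (any(components < 0)) abort("uncertainty components must be non-negative")
  structure(list(components = components,
                 total = sqrt(sum(components^2))),
            class = "mu_uncertainty")
}

#' @rdname propagate_uncertainty
#' @param model Budget variant: correction-based or analytical.
#' @param field Field-size regime: `"large"` (> 5x5 cm2) or `"small"`.
#' @export
uncertainty_budget <- function(model = c("correction", "analytical"),
                               field = c("large", "small")) {
  model <- match.arg(model); field <- match.arg(field)
  fsf <- if (field == "large") 1.0 else 3.0
  if (model == "correction") {
    c(ROF = 0.5, SOBPF = 0.5, RSF = 1.0, ISF_OCF = 0.5, OCR = 1.0,
      FSF = fsf, GACF = 0.5)
  } else {
    c(basic_and_shift = 1.5, ISF_OCF = 0.5, OCR = 1.0, FSF = fsf, GACF = 0.5)
  }
}

#' @export
print.mu_uncertainty <- function(x, ...) {
  cat("<mu_uncertainty> components (%):\n")
  print(round(x$components, 3))
  cat(sprintf("total (quadrature): %.3f%%\n", x$total))
  invisible(x)
}

#' @rdname propagate_uncertainty
#' @param x A `mu_uncertainty` object.
#' @param ... Unused.
#' @export
tidy.mu_uncertainty <- function(x, ...) {
  tibble(component = names(x$components), percent = unname(x$components))
}

#' @rdname propagate_uncertainty
#' @export
glance.mu_uncertainty <- function(x, ...) {
  tibble(n_components = length(x$components), total = x$total)
}
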