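#' Bilinear interpolation on a rectangular grid
#'
#' Thin wrapper around [pracma::interp2()] with the grid supplied as strictly
#' increasing axes `x`, `y` and a matrix `z` with `z[i, j]` the value at
#' `(x[i], y[j])`.  Queries outside the grid raise an error: the commissioning
#' tables are measured to cover the clinical domain, and no silent
#' extrapolation is permitted anywhere in this package.
#'
#' @param x,y Strictly increasing grid axes.
#' @param z Matrix of values, `length(x)` by `length(y)`.
#' @param xq,yq Query coordinates (equal-length vectors).
#' @return Interpolated values, exact at grid nodes.
#' @export
interp_bilinear <- function(x, y, z, xq, yq) {
  stopifnot(is.matrix(z), nrow(z) == length(x), ncol(z) == length(y))
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    abort("grid axes must be strictly increasing")
  }
  eps <- 1e-9
  out_of_range <- xq < x[1] - eps | xq > x[length(x)] + eps |
    yq < y[1] - eps | yq > y[length(y)] + eps
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    abort(sprintf("query (%.4g, %.4g) outside grid [%g, %g] x [%g, %g]; no extrapolation",
                  xq[i], yq[i], x[1], x[length(x)], y[1], y[length(y)]))
  }
  xq <- pmin(pmax(xq, x[1]), x[length(x)])
  yq <- pmin(pmax(yq, y[1]), y[length(y)])
  # pracma::interp2 expects Z with length(y) rows and length(x) columns
  pracma::interp2(x, y, t(z), xq, yq, method = "linear")
}

#' Piecewise-linear interpolation with strict bounds
#'
#' @noRd
interp1_strict <- function(x, y, xq, what = "value") {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  eps <- 1e-9
  if (length(x) == 1) {
    if (any(abs(xq - x) > eps)) {
      abort(sprintf("%s grid has a single node at %g; query off-node not allowed", what, x))
    }
    return(rep(y, length(xq)))
  }
  if (any(xq < x[1] - eps | xq > x[length(x)] + eps)) {
    bad <- xq[xq < x[1] - eps | xq > x[length(x)] + eps][1]
    abort(sprintf("%s = %.4g outside commissioned span [%g, %g]; no extrapolation",
                  what, bad, x[1], x[length(x)]))
  }
  xq <- pmin(pmax(xq, x[1]), x[length(x)])
  approx(x, y, xout = xq, method = "linear", ties = "ordered")$y
}

#' Commissioning factor tables
#'
#' Container for all correction-factor tables of the correction-based output
#' model: the absolute reference output `psi_o` (cGy/MU) and the relative
#' factors ROF (per option), SOBPF (per option, vs modulation), RSF (per
#' option, range x modulation grid with placeholder flags), OCR (per option,
#' lateral x/y grid), FSF (per option, vs equivalent field size) and GACF (per
#' group, vs gantry angle).  Every factor is the ratio of a measured output to
#' the output under the corresponding reference conditions, so the tables obey
#' normalization invariants checked by [validate_tables()]: ROF of the
#' calibration option is 1, each option's SOBPF at its ROF modulation is 1,
#' each RSF row at the largest commissioned range is 1, OCR on the central
#' axis is 1, FSF at the group reference field is 1, and GACF at gantry 0 is 1.
#'
#' @param psi_o Absolute output (cGy/MU) for the calibration beam.
#' @param rof Tibble `option`, `factor`.
#' @param sobpf Tibble `option`, `M`, `factor`.
#' @param rsf Tibble `option`, `R`, `M`, `factor`, `placeholder` (logical;
#'   `factor` may be `NA` for unfilled placeholder cells, see
#'   [fill_rsf_placeholders()]).
#' @param ocr Tibble `option`, `x`, `y`, `factor` on a rectangular grid.
#' @param fsf Tibble `option`, `field`, `factor` (field descriptors as in
#'   [field_size()]).
#' @param gacf Tibble `group`, `angle`, `factor`.
#' @param reference List describing the calibration beam (option, R, M, field,
#'   angle).
#' @return An object of class `mu_tables`.
#' @seealso [s250_tables()] for the published factors shipped with the
#'   package, [tables_from_campaign()] to build tables from measurements.
#' @export
mu_tables <- function(psi_o, rof, sobpf, rsf, ocr, fsf, gacf,
                      reference = list(option = 20, R = 15.0, M = 10.0,
                                       field = "10x10", angle = 0)) {
  stopifnot(is.numeric(psi_o), length(psi_o) == 1, psi_o > 0)
  rof <- as_tibble(rof); sobpf <- as_tibble(sobpf); rsf <- as_tibble(rsf)
  ocr <- as_tibble(ocr); fsf <- as_tibble(fsf); gacf <- as_tibble(gacf)
  stopifnot(all(c("option", "factor") %in% names(rof)),
            all(c("option", "M", "factor") %in% names(sobpf)),
            all(c("option", "R", "M", "factor") %in% names(rsf)),
            all(c("option", "x", "y", "factor") %in% names(ocr)),
            all(c("option", "field", "factor") %in% names(fsf)),
            all(c("group", "angle", "factor") %in% names(gacf)))
  if (!("placeholder" %in% names(rsf))) rsf$placeholder <- FALSE
  rsf$placeholder <- as.logical(rsf$placeholder)
  rof$factor <- as.numeric(rof$factor)
  sobpf$factor <- as.numeric(sobpf$factor)
  rsf$factor <- as.numeric(rsf$factor)
  ocr$factor <- as.numeric(ocr$factor)
  fsf$factor <- as.numeric(fsf$factor)
  gacf$factor <- as.numeric(gacf$factor)
  attr(ocr, "out.attrs") <- NULL
  attr(rsf, "out.attrs") <- NULL
  structure(list(psi_o = psi_o, reference = reference, rof = rof,
                 sobpf = sobpf, rsf = rsf, ocr = ocr, fsf = fsf, gacf = gacf),
            class = "mu_tables")
}

#' @export
print.mu_tables <- function(x, ...) {
  cat("<mu_tables>\n")
  cat(sprintf("  reference output psi_o: %.4g cGy/MU (option %s, R = %s, M = %s)\n",
              x$psi_o, x$reference$option, x$reference$R, x$reference$M))
  cat(sprintf("  ROF: %d options | SOBPF: %d points | RSF: %d cells (%d placeholders)\n",
              nrow(x$rof), nrow(x$sobpf), nrow(x$rsf), sum(x$rsf$placeholder)))
  cat(sprintf("  OCR: %d points | FSF: %d points | GACF: %d points\n",
              nrow(x$ocr), nrow(x$fsf), nrow(x$gacf)))
  invisible(x)
}

#' Check commissioning-table normalization invariants
#'
#' Emits a warning for each violated invariant (see [mu_tables()]) and returns
#' the issues invisibly as a character vector (empty when all hold).
#'
#' @param tables A [mu_tables()] object.
#' @param tol Numeric tolerance on the normalization checks.
#' @export
validate_tables <- function(tables, tol = 1e-6) {
  issues <- character()
  ref_opt <- tables$reference$option
  r0 <- tables$rof$factor[tables$rof$option == ref_opt]
  if (length(r0) != 1 || abs(r0 - 1) > tol) {
    issues <- c(issues, sprintf("ROF of calibration option %d is not 1.00", ref_opt))
  }
  ax_bad <- tables$sobpf |>
    dplyr::group_by(.data$option) |>
    dplyr::summarise(dup = anyDuplicated(.data$M) > 0) |>
    dplyr::filter(.data$dup)
  if (nrow(ax_bad) > 0) {
    issues <- c(issues, paste0("duplicate SOBPF modulation nodes for option(s) ",
                               paste(ax_bad$option, collapse = ", ")))
  }
  top <- tables$rsf |>
    dplyr::group_by(.data$option) |>
    dplyr::filter(.data$R == max(.data$R)) |>
    dplyr::ungroup()
  if (any(abs(top$factor - 1) > tol, na.rm = TRUE)) {
    issues <- c(issues, "RSF row at the largest commissioned R is not 1.00 for all M")
  }
  ocr0 <- tables$ocr |> dplyr::filter(.data$x == 0, .data$y == 0)
  if (nrow(ocr0) > 0 && any(abs(ocr0$factor - 1) > tol)) {
    issues <- c(issues, "OCR on the central axis is not 1.00")
  }
  g0 <- tables$gacf |> dplyr::filter(.data$angle == 0)
  if (nrow(g0) > 0 && any(abs(g0$factor - 1) > tol)) {
    issues <- c(issues, "GACF at gantry angle 0 is not 1.00")
  }
  for (msg in issues) warn(msg)
  invisible(issues)
}

#' Look up the relative output factor (ROF)
#'
#' The ROF is a per-option scalar: the ratio of the option's output at its
#' deepest range and reference modulation to the calibration option's output.
#' It is stored exactly, with no interpolation.
#'
#' @param tables A [mu_tables()] object.
#' @param option Option number(s).
#' @return Numeric factor(s).
#' @export
rof_factor <- function(tables, option) {
  i <- match(option, tables$rof$option)
  if (anyNA(i)) {
    abort(paste0("no ROF stored for option(s): ",
                 paste(option[is.na(i)], collapse = ", ")))
  }
  tables$rof$factor[i]
}

#' Interpolate the SOBP factor (SOBPF)
#'
#' Piecewise-linear interpolation of the per-option SOBP factor over the
#' measured modulation grid.  Exact at grid nodes; queries outside the
#' commissioned span raise an error.
#'
#' @inheritParams rof_factor
#' @param M Modulation width(s) (g/cm2); `option` is recycled if scalar.
#' @export
sobpf_factor <- function(tables, option, M) {
  if (length(option) == 1) option <- rep(option, length(M))
  stopifnot(length(option) == length(M))
  out <- numeric(length(M))
  for (o in unique(option)) {
    g <- tables$sobpf[tables$sobpf$option == o, ]
    if (nrow(g) == 0) abort(paste0("no SOBPF grid for option ", o))
    sel <- option == o
    out[sel] <- interp1_strict(g$M, g$factor, M[sel], what = "modulation")
  }
  out
}

#' @noRd
rsf_grid <- function(tables, o) {
  g <- tables$rsf[tables$rsf$option == o, ]
  if (nrow(g) == 0) abort(paste0("no RSF grid for option ", o))
  Rax <- sort(unique(g$R)); Max <- sort(unique(g$M))
  z <- matrix(NA_real_, length(Rax), length(Max))
  ph <- matrix(FALSE, length(Rax), length(Max))
  z[cbind(match(g$R, Rax), match(g$M, Max))] <- g$factor
  ph[cbind(match(g$R, Rax), match(g$M, Max))] <- g$placeholder
  if (any(is.na(z))) {
    abort(paste0("RSF grid for option ", o,
                 " is not rectangular or has unfilled placeholder cells; ",
                 "run fill_rsf_placeholders() first"))
  }
  list(R = Rax, M = Max, z = z, ph = ph)
}

#' Interpolate the range shifter factor (RSF)
#'
#' Bilinear interpolation of the per-option RSF on its commissioned range x
#' modulation grid.  Exact at grid nodes.  Placeholder cells (extrapolated
#' values at grid corners where M > R is not deliverable) participate in the
#' interpolation, but any query whose interpolation cell touches a placeholder
#' corner is flagged.
#'
#' @inheritParams rof_factor
#' @param R,M Range and modulation (g/cm2), equal-length vectors (a scalar
#'   `option` is recycled).
#' @param detail If `TRUE`, return a tibble with columns `factor` and
#'   `placeholder` (flag); otherwise a numeric vector carrying the flag as
#'   attribute `"placeholder"`.
#' @export
rsf_factor <- function(tables, option, R, M, detail = FALSE) {
  n <- max(length(R), length(M))
  R <- rep_len(R, n); M <- rep_len(M, n)
  if (length(option) == 1) option <- rep(option, n)
  out <- numeric(n); flag <- logical(n)
  for (o in unique(option)) {
    g <- rsf_grid(tables, o)
    sel <- which(option == o)
    out[sel] <- interp_bilinear(g$R, g$M, g$z, R[sel], M[sel])
    # a query is flagged if any corner of its bracketing cell is a placeholder
    iR <- pmin(pmax(findInterval(R[sel], g$R), 1), length(g$R) - 1)
    iM <- pmin(pmax(findInterval(M[sel], g$M), 1), length(g$M) - 1)
    if (length(g$R) == 1) iR <- rep(1, length(sel))
    if (length(g$M) == 1) iM <- rep(1, length(sel))
    flag[sel] <- g$ph[cbind(iR, iM)] | g$ph[cbind(iR + 1, iM)] |
      g$ph[cbind(iR, iM + 1)] | g$ph[cbind(iR + 1, iM + 1)]
  }
  if (detail) return(tibble(factor = out, placeholder = flag))
  attr(out, "placeholder") <- flag
  out
}

#' Fill non-deliverable RSF grid cells by log-fit extrapolation
#'
#' Rectangular RSF grids can contain corners where the modulation exceeds the
#' range; such beams are not deliverable, so the cell cannot be measured, yet
#' 2-D interpolation needs a value there.  Each incomplete grid row is
#' extended by evaluating a curve `c0 + c1 * log(M)` fitted by least squares
#' to the row's measured cells (at least 3 required).  Filled cells are
#' flagged `placeholder = TRUE`; complete rows are left untouched.
#'
#' @param tables A [mu_tables()] object.
#' @param option Option(s) to fill; default all.
#' @return The tables with placeholder cells filled.
#' @export
fill_rsf_placeholders <- function(tables, option = NULL) {
  rsf <- tables$rsf
  opts <- if (is.null(option)) unique(rsf$option) else option
  for (o in opts) {
    idx <- which(rsf$option == o)
    g <- rsf[idx, ]
    for (Rv in unique(g$R)) {
      row_i <- idx[g$R == Rv]
      miss <- is.na(rsf$factor[row_i])
      if (!any(miss)) next
      mM <- rsf$M[row_i][!miss]; mF <- rsf$factor[row_i][!miss]
      if (length(mM) < 3) {
        abort(sprintf(
          "cannot extrapolate RSF row (option %s, R = %g): only %d measured points (need >= 3)",
          o, Rv, length(mM)))
      }
      fit <- lm(mF ~ log(mM))
      fillM <- rsf$M[row_i][miss]
      rsf$factor[row_i[miss]] <- unname(coef(fit)[1] + coef(fit)[2] * log(fillM))
      rsf$placeholder[row_i[miss]] <- TRUE
    }
  }
  tables$rsf <- rsf
  tables
}

#' Interpolate the off-center ratio (OCR)
#'
#' Bilinear interpolation of the per-option lateral dose profile, normalized
#' to 1.00 on the central axis.  The measured profiles are not radially
#' symmetric, so a full 2-D table is used rather than a radial curve.
#'
#' @inheritParams rof_factor
#' @param x,y Lateral offsets (cm) in the beam's-eye view.
#' @export
ocr_factor <- function(tables, option, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (length(option) == 1) option <- rep(option, n)
  out <- numeric(n)
  for (o in unique(option)) {
    g <- tables$ocr[tables$ocr$option == o, ]
    if (nrow(g) == 0) abort(paste0("no OCR grid for option ", o))
    sel <- which(option == o)
    xax <- sort(unique(g$x)); yax <- sort(unique(g$y))
    if (length(xax) == 1 && length(yax) == 1) {
      if (any(abs(x[sel] - xax) > 1e-9 | abs(y[sel] - yax) > 1e-9)) {
        abort(paste0("OCR grid for option ", o,
                     " has a single node; off-axis query not allowed"))
      }
      out[sel] <- g$factor[1]
      next
    }
    z <- matrix(NA_real_, length(xax), length(yax))
    z[cbind(match(g$x, xax), match(g$y, yax))] <- g$factor
    if (any(is.na(z))) abort(paste0("OCR grid for option ", o, " is not rectangular"))
    out[sel] <- interp_bilinear(xax, yax, z, x[sel], y[sel])
  }
  out
}

#' Resample a lateral profile grid
#'
#' Detector arrays sample the lateral profile coarsely (10 mm center-to-center
#' spacing); for tabulation the profile is resampled on a fine uniform grid
#' (0.5 mm default) by bilinear interpolation.  The resampled grid agrees with
#' the raw grid exactly at coincident points and preserves the extent.
#'
#' @param ocr Tibble with columns `x`, `y`, `factor` on a uniform rectangular
#'   grid (a single option's profile).
#' @param spacing Output grid spacing (cm); default 0.05 cm = 0.5 mm.
#' @return A tibble `x`, `y`, `factor` at the new spacing.
#' @export
resample_ocr <- function(ocr, spacing = 0.05) {
  ocr <- as_tibble(ocr)
  xax <- sort(unique(ocr$x)); yax <- sort(unique(ocr$y))
  dx <- diff(xax); dy <- diff(yax)
  if (length(dx) == 0 || length(dy) == 0) abort("OCR grid must be 2-D to resample")
  if (max(abs(dx - dx[1])) > 1e-9 || max(abs(dy - dy[1])) > 1e-9) {
    abort("raw OCR grid spacing is not uniform")
  }
  z <- matrix(NA_real_, length(xax), length(yax))
  z[cbind(match(ocr$x, xax), match(ocr$y, yax))] <- ocr$factor
  if (any(is.na(z))) abort("OCR grid is not rectangular")
  xq <- seq(xax[1], xax[length(xax)], by = spacing)
  yq <- seq(yax[1], yax[length(yax)], by = spacing)
  grid <- expand.grid(x = xq, y = yq, KEEP.OUT.ATTRS = FALSE)
  grid$factor <- interp_bilinear(xax, yax, z, grid$x, grid$y)
  as_tibble(grid)
}

#' Interpolate the field size factor (FSF)
#'
#' Field descriptors are reduced to an equivalent square side ([field_size()])
#' and the factor interpolated linearly between measured entries.  FSF is
#' measured for three options per group; other options use the nearest
#' measured option within their group.  Queries below the smallest measured
#' field raise an error advising direct measurement (small-field outputs must
#' be measured, not interpolated) unless `allow_small = TRUE`.
#'
#' @inheritParams rof_factor
#' @param field Field descriptor(s), see [field_size()].
#' @param catalog Option catalog (for group membership).
#' @param allow_small Permit queries below the smallest measured field.
#' @export
fsf_factor <- function(tables, option, field, catalog = option_catalog(),
                       allow_small = FALSE) {
  n <- max(length(option), length(field))
  option <- rep_len(option, n); field <- rep_len(field, n)
  s <- field_size(field)
  out <- numeric(n)
  measured <- unique(tables$fsf$option)
  for (o in unique(option)) {
    sel <- which(option == o)
    src <- o
    if (!(o %in% measured)) {
      grp <- catalog$group[catalog$option == o]
      cand <- measured[catalog$group[match(measured, catalog$option)] == grp]
      if (length(cand) == 0) abort(paste0("no FSF measured in group for option ", o))
      src <- cand[which.min(abs(cand - o))]
    }
    g <- tables$fsf[tables$fsf$option == src, ]
    gs <- field_size(g$field)
    sq <- s[sel]
    if (any(sq < min(gs) - 1e-9)) {
      if (!allow_small) {
        abort(sprintf(paste0(
          "field smaller than the smallest measured field (%.2f cm equivalent square) ",
          "for option %s: small-field outputs should be measured directly ",
          "(set allow_small = TRUE to override)"), min(gs), o))
      }
      sq <- pmax(sq, min(gs))  # override: clamp to the smallest measured field
    }
    out[sel] <- interp1_strict(gs, g$factor, sq, what = "equivalent field size")
  }
  out
}

#' Interpolate the gantry angle correction factor (GACF)
#'
#' The output varies with gantry angle because the accelerator rotates with
#' the gantry; all options within a group share one factor curve.
#' Piecewise-linear interpolation along the rotation arc (so interpolation
#' works across the 355 -> 0 degree wrap).
#'
#' @inheritParams rof_factor
#' @param group Option group (`"large"`, `"deep"` or `"small"`), recycled.
#' @param angle Gantry angle(s), degrees, within the valid arc.
#' @export
gacf_factor <- function(tables, group, angle) {
  n <- max(length(group), length(angle))
  group <- rep_len(group, n); angle <- rep_len(angle, n)
  tq <- arc_position(angle)
  out <- numeric(n)
  for (gr in unique(group)) {
    g <- tables$gacf[tables$gacf$group == gr, ]
    if (nrow(g) == 0) abort(paste0("no GACF grid for group ", gr))
    sel <- which(group == gr)
    out[sel] <- interp1_strict(arc_position(g$angle), g$factor, tq[sel],
                               what = "gantry arc position")
  }
  out
}

#' Read and write commissioning tables
#'
#' Tables are stored as a single JSON bundle holding the reference output,
#' the reference beam description and one data block per factor type.
#' `write_tables()` followed by `read_tables()` reproduces all numeric content
#' exactly (values are written at full precision; pass `digits = 4` to write
#' rounded factors in the conventional 4-decimal table format instead).
#'
#' @param path File path.
#' @param tables A [mu_tables()] object.
#' @param digits Number of decimal places on write; `NA` (default) writes full
#'   precision.
#' @return `read_tables()`: a [mu_tables()] object (normalization invariants
#'   are checked on read, emitting warnings); `write_tables()`: the path,
#'   invisibly.
#' @export
read_tables <- function(path) {
  if (!file.exists(path)) abort(paste0("tables file not found: ", path))
  raw <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort(paste0("cannot parse tables file ", path,
                                                   ": ", conditionMessage(e))))
  for (block in c("psi_o", "rof", "sobpf", "rsf", "ocr", "fsf", "gacf")) {
    if (is.null(raw[[block]])) {
      abort(paste0("tables file ", path, " is missing the '", block, "' block"))
    }
  }
  tb <- mu_tables(psi_o = raw$psi_o,
                  rof = raw$rof, sobpf = raw$sobpf, rsf = raw$rsf,
                  ocr = raw$ocr, fsf = raw$fsf, gacf = raw$gacf,
                  reference = raw$reference)
  validate_tables(tb)
  tb
}

#' @rdname read_tables
#' @export
write_tables <- function(tables, path, digits = NA) {
  obj <- unclass(tables)
  if (!is.na(digits)) {
    for (block in c("rof", "sobpf", "rsf", "ocr", "fsf", "gacf")) {
      obj[[block]]$factor <- round(obj[[block]]$factor, digits)
    }
  }
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = FALSE, na = "null")
  invisible(path)
}

#' Published commissioning factors for the S250 system
#'
#' Builds a [mu_tables()] object from the published factor tables shipped with
#' the package: the per-option relative output factors, the range-shifter
#' grids for options 1, 13 and 20 (including the extrapolated placeholder
#' cells), and the field size factors for nine options.  The absolute
#' reference output is 1.06 cGy/MU (option 20, R = 15.0, M = 10.0 g/cm2).
#' SOBPF, OCR and GACF content beyond their normalization nodes is
#' site-measured and not published, so those tables contain only the
#' reference nodes (factor 1 at the ROF modulation, the central axis, and
#' gantry 0); predictions under reference conditions are exact, and any other
#' query raises rather than inventing data.
#'
#' @return A [mu_tables()] object.
#' @examples
#' tb <- s250_tables()
#' rof_factor(tb, 13)
#' @export
s250_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "protonmu")
  rof_csv <- read.csv(ext("rof_table.csv"))
  rsf_csv <- read.csv(ext("rsf_table.csv"))
  fsf_csv <- read.csv(ext("fsf_table.csv"))
  catalog <- option_catalog()
  sobpf <- tibble(option = rof_csv$option, M = rof_csv$M, factor = 1.0)
  ocr <- tibble(option = rof_csv$option, x = 0, y = 0, factor = 1.0)
  gacf <- tibble(group = c("large", "deep", "small"), angle = 0, factor = 1.0)
  mu_tables(psi_o = 1.06,
            rof = tibble(option = rof_csv$option, factor = rof_csv$rof),
            sobpf = sobpf,
            rsf = as_tibble(rsf_csv),
            ocr = ocr,
            fsf = as_tibble(fsf_csv),
            gacf = gacf)
}
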