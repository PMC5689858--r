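#' Machine option catalog
#'
#' The beam delivery system has 24 discrete beamline configurations
#' ("options"), partitioned into three groups: *large* (options 1-12, large
#' applicator, 20x20 cm2 reference field), *deep* (13-17) and *small* (18-24)
#' (small applicator, 10x10 cm2 reference field).  Each option covers a window
#' of ranges `[R_min, R_max]` (water-equivalent g/cm2, distal 90% dose) and
#' modulation widths `[M_min, M_max]` (distal 90% to proximal 95%), both on a
#' 0.1 g/cm2 step grid.
#'
#' `option_catalog()` returns the default machine definition shipped with the
#' package; `read_catalog()` reads a user-supplied JSON machine definition with
#' the same fields (option hardware is machine specific, so sites are expected
#' to edit this file).  Per-option range windows default to 2.4 g/cm2 below the
#' option's largest commissioned range, clipped to the group minimum; effective
#' source-to-axis distances (ESAD, cm) default to a linear ramp in `R_max`
#' anchored at the commissioned extremes 171.9 cm and 180.8 cm.
#'
#' @param path Path to a JSON machine-definition file.
#' @return A tibble with one row per option and columns `option`, `group`,
#'   `R_min`, `R_max`, `M_min`, `M_max`, `applicator`, `ref_field`, `ESAD`,
#'   `R_L` (lowest commissioned range, equal to `R_min`), and the per-option
#'   reference conditions `rof_R`, `rof_M` at which the relative output factor
#'   is measured.
#' @examples
#' option_catalog()
#' @export
option_catalog <- function() {
  read_catalog(system.file("extdata", "option_catalog.json", package = "protonmu"))
}

#' @rdname option_catalog
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  cat_df <- as_tibble(jsonlite::fromJSON(path))
  needed <- c("option", "group", "R_min", "R_max", "M_min", "M_max",
              "applicator", "ref_field", "ESAD", "R_L", "rof_R", "rof_M")
  missing <- setdiff(needed, names(cat_df))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing fields: ", paste(missing, collapse = ", ")))
  }
  stopifnot(all(cat_df$R_min < cat_df$R_max),
            all(cat_df$ESAD > 0),
            !anyDuplicated(cat_df$option))
  cat_df
}

#' Gantry arc coordinate
#'
#' The gantry rotates through a 190 degree arc from 355 degrees to 185 degrees
#' with 0 degrees facing down.  Angles are stored in [0, 360); the valid set is
#' the arc [0, 185] union [355, 360).  `arc_position()` maps an angle to its
#' distance (degrees) along the rotation path from the 355-degree end;
#' `angle_distance()` is the resulting arc-length metric, used for gantry
#' factor interpolation across the 355 -> 0 wrap.
#'
#' @param a,b Gantry angles in degrees, within the valid arc.
#' @return `arc_position()`: position in [0, 190]; `angle_distance()`:
#'   non-negative separation in degrees along the arc.
#' @examples
#' angle_distance(355, 5)   # 10, across the wrap
#' angle_distance(355, 185) # 190, the full arc
#' @export
angle_distance <- function(a, b) {
  abs(arc_position(a) - arc_position(b))
}

#' @rdname angle_distance
#' @export
arc_position <- function(a) {
  if (any(a < 0 | a >= 360)) abort("gantry angle must lie in [0, 360)")
  t <- (a - 355) %% 360
  if (any(t > 190 + 1e-9)) {
    bad <- a[t > 190 + 1e-9]
    abort(paste0("gantry angle outside the 355-185 degree arc: ",
                 paste(bad, collapse = ", ")))
  }
  t
}

#' Validate beam specifications against the option catalog
#'
#' Checks each beam against its option's commissioned limits: `R` within
#' `[R_min, R_max]`, `M` within `[M_min, M_max]`, `M <= R` (a modulation wider
#' than the range would place a high-dose region outside the patient, and is
#' not an allowable machine entry), and the gantry angle within the valid arc.
#'
#' @param beams A data frame with columns `option`, `R`, `M`, and optionally
#'   `angle` (degrees, default 0), `field`, `dz_p`, `dz`, `x`, `y`.
#' @param catalog Option catalog, see [option_catalog()].
#' @return The input beams as a tibble, with defaulted columns filled in.
#'   Invalid beams raise an error naming the violated limit.
#' @examples
#' validate_beams(data.frame(option = 20, R = 15, M = 10))
#' @export
validate_beams <- function(beams, catalog = option_catalog()) {
  beams <- as_tibble(beams)
  stopifnot(all(c("option", "R", "M") %in% names(beams)))
  if (!all(beams$option %in% catalog$option)) {
    abort(paste0("unknown option(s): ",
                 paste(setdiff(beams$option, catalog$option), collapse = ", ")))
  }
  defaults <- list(angle = 0, dz_p = 0, dz = 0, x = 0, y = 0)
  for (nm in names(defaults)) {
    if (is.null(beams[[nm]])) beams[[nm]] <- defaults[[nm]]
  }
  if (is.null(beams[["field"]])) {
    beams$field <- catalog$ref_field[match(beams$option, catalog$option)]
  }
  spec <- catalog[match(beams$option, catalog$option), ]
  bad_R <- beams$R < spec$R_min - 1e-9 | beams$R > spec$R_max + 1e-9
  if (any(bad_R)) {
    i <- which(bad_R)[1]
    abort(sprintf("R = %.1f outside [%.1f, %.1f] for option %d",
                  beams$R[i], spec$R_min[i], spec$R_max[i], beams$option[i]))
  }
  bad_M <- beams$M < spec$M_min - 1e-9 | beams$M > spec$M_max + 1e-9
  if (any(bad_M)) {
    i <- which(bad_M)[1]
    abort(sprintf("M = %.1f outside [%.1f, %.1f] for option %d",
                  beams$M[i], spec$M_min[i], spec$M_max[i], beams$option[i]))
  }
  over <- beams$M > beams$R + 1e-9
  if (any(over)) {
    i <- which(over)[1]
    abort(sprintf("modulation exceeds range (M = %.1f > R = %.1f) for option %d",
                  beams$M[i], beams$R[i], beams$option[i]))
  }
  arc_position(beams$angle)  # errors if outside arc
  beams
}

#' Construct a single beam specification
#'
#' Convenience wrapper building a one-row beam tibble for [predict_output()].
#'
#' @param option Option number (1-24).
#' @param R Range, depth of the distal 90% dose (g/cm2).
#' @param M Modulation width, distal 90% to proximal 95% (g/cm2).
#' @param field Field descriptor at the isocenter plane: `"NxN"` for squares or
#'   `"circD"` for circles of diameter D cm.
#' @param angle Gantry angle (degrees) within the 355-185 arc.
#' @param dz_p Longitudinal distance (cm) of the calibration point from the
#'   SOBP center: negative downstream, positive upstream.
#' @param dz Longitudinal offset (cm) between the SOBP center and the
#'   isocenter.
#' @param x,y Lateral offsets (cm) of the point in the beam's-eye view.
#' @return A one-row tibble.
#' @examples
#' beam_spec(20, R = 15, M = 10)
#' @export
beam_spec <- function(option, R, M, field = NULL, angle = 0,
                      dz_p = 0, dz = 0, x = 0, y = 0) {
  b <- tibble(option = option, R = R, M = M, angle = angle,
              dz_p = dz_p, dz = dz, x = x, y = y)
  if (!is.null(field)) b$field <- field
  b
}

#' Equivalent square side of a field descriptor
#'
#' Reduces a field descriptor to one scalar for field-size interpolation: the
#' side length for a square `"NxN"` (geometric mean side for a rectangle
#' `"NxM"`), and the equivalent-square side `D * sqrt(pi) / 2` for a circle
#' `"circD"` — the standard dosimetric equivalent-area convention.
#'
#' @param field Character vector of field descriptors.
#' @return Numeric vector of equivalent square sides (cm).
#' @examples
#' field_size(c("10x10", "circ14"))
#' @export
field_size <- function(field) {
  vapply(field, function(f) {
    f <- tolower(trimws(f))
    if (grepl("^circ", f)) {
      d <- suppressWarnings(as.numeric(sub("^circ", "", f)))
      if (is.na(d) || d <= 0) abort(paste0("cannot parse field descriptor: ", f))
      return(d * sqrt(pi) / 2)
    }
    if (grepl("^[0-9.]+x[0-9.]+$", f)) {
      ab <- as.numeric(strsplit(f, "x")[[1]])
      if (any(is.na(ab)) || any(ab <= 0)) {
        abort(paste0("cannot parse field descriptor: ", f))
      }
      return(sqrt(ab[1] * ab[2]))
    }
    abort(paste0("cannot parse field descriptor: ", f))
  }, numeric(1), USE.NAMES = FALSE)
}
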