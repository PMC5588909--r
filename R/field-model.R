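# Test-pattern geometry, the perimetric decibel scale and visual-field
# containers.
#
# Coordinate convention: degrees of visual angle in a per-eye frame with
# temporal = +x for the right eye (so the left-eye pattern is the mirror
# image, temporal = -x becomes +|x| after negation) and superior = +y.

#' Decibel reference: 0 dB corresponds to a 10,000 apostilb increment
#' (10,000 / pi cd/m^2), the conventional maximum of bowl perimeters.
#' @keywords internal
DB0_INCREMENT_CDM2 <- 10000 / pi

#' Default stimulus parameters (Goldmann III, 200 ms, 10 cd/m^2 background)
#' and the displayable dB range of the instrument.
#' @keywords internal
SVOP_LEVEL_RANGE_DB <- c(14, 40)

#' Generate a perimetric test pattern
#'
#' Builds the standard 24-2 grid of 54 test locations: rows every 6 degrees
#' offset 3 degrees from the horizontal and vertical meridians, covering
#' 24 degrees of eccentricity with the nasal edge of the two paracentral
#' rows extended to 27 degrees.  The two locations straddling the
#' physiologic blind spot (15 degrees temporal, +/-3 degrees vertical) are
#' flagged.  Left-eye patterns are the mirror image of right-eye patterns
#' (x negated).
#'
#' @param pattern_name Pattern identifier; only `"24-2"` is supported.
#' @param eye `"right"` or `"left"`.
#' @return An object of class `svop_pattern`: a data frame with columns
#'   `x_deg`, `y_deg` (degrees of visual angle, temporal-positive for the
#'   right eye, superior-positive) and `is_blind_spot`, with attributes
#'   `pattern_name` and `eye`.
#' @examples
#' p <- generate_pattern("24-2", "right")
#' nrow(p)                     # 54
#' sum(p$is_blind_spot)        # 2
#' @export
generate_pattern <- function(pattern_name = "24-2", eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (!identical(pattern_name, "24-2")) {
    stop("unsupported test pattern: ", pattern_name)
  }
  # Row composition of the 24-2 grid in the right-eye frame
  # (temporal = +x, nasal = -x; nasal extension to -27 on the +/-3 rows).
  row_x <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-27, -21, -15, -9, -3, 3, 9, 15, 21)
  )
  xs <- numeric(0); ys <- numeric(0)
  for (ay in c(21, 15, 9, 3)) {
    for (sy in c(1, -1)) {
      x_row <- row_x[[as.character(ay)]]
      xs <- c(xs, x_row)
      ys <- c(ys, rep(sy * ay, length(x_row)))
    }
  }
  if (eye == "left") xs <- -xs
  pat <- data.frame(
    x_deg = xs,
    y_deg = ys,
    is_blind_spot = (xs == if (eye == "right") 15 else -15) & abs(ys) == 3
  )
  # stable ordering: superior to inferior, nasal to temporal
  pat <- pat[order(-pat$y_deg, pat$x_deg), , drop = FALSE]
  rownames(pat) <- NULL
  structure(pat,
            pattern_name = pattern_name, eye = eye,
            class = c("svop_pattern", "data.frame"))
}

#' @export
print.svop_pattern <- function(x, ...) {
  cat(sprintf("<svop_pattern> %s, %s eye: %d locations (%d blind-spot)\n",
              attr(x, "pattern_name"), attr(x, "eye"),
              nrow(x), sum(x$is_blind_spot)))
  invisible(x)
}

#' Convert a sensitivity level in dB to a luminance increment
#'
#' Perimetric decibels express attenuation of the instrument's maximum
#' stimulus: increment = L0 * 10^(-dB/10) with L0 = 10,000 apostilb
#' (10,000/pi cd/m^2).  Higher dB therefore means a dimmer stimulus.  The
#' stimulus as displayed rides on the background, so its absolute luminance
#' is `db_to_increment(level) + background`.
#'
#' @param level_db Sensitivity level(s) in dB, must be >= 0.
#' @return Luminance increment(s) in cd/m^2.
#' @examples
#' db_to_increment(0)             # 3183.1, the 0 dB reference
#' db_to_increment(14) + 10       # ~136.7, the brightest displayable stimulus
#' @export
db_to_increment <- function(level_db) {
  if (any(!is.finite(level_db)) || any(level_db < 0)) {
    stop("level_db must be finite and >= 0")
  }
  DB0_INCREMENT_CDM2 * 10^(-level_db / 10)
}

#' Convert a luminance increment to the sensitivity level in dB
#'
#' Exact inverse of [db_to_increment()].
#'
#' @param increment_cdm2 Luminance increment(s) in cd/m^2, must be > 0.
#' @return Level(s) in dB.
#' @export
increment_to_db <- function(increment_cdm2) {
  if (any(!is.finite(increment_cdm2)) || any(increment_cdm2 <= 0)) {
    stop("increment_cdm2 must be finite and > 0")
  }
  -10 * log10(increment_cdm2 / DB0_INCREMENT_CDM2)
}

#' Truncate thresholds at a comparison floor
#'
#' An LCD-based instrument cannot display stimuli brighter than its panel
#' allows (here 14 dB), so thresholds from a comparison device that go
#' below that floor are truncated to it before any agreement statistic is
#' computed.  `NA` values pass through unchanged.
#'
#' @param thresholds Numeric vector of thresholds in dB.
#' @param floor_db Comparison floor in dB (default 14, the instrument's
#'   minimum displayable level).
#' @return Vector of the same length with values below `floor_db` replaced
#'   by `floor_db`.
#' @examples
#' truncate_for_comparison(c(5, 20, 14))   # 14 20 14
#' @export
truncate_for_comparison <- function(thresholds, floor_db = SVOP_LEVEL_RANGE_DB[1]) {
  pmax(thresholds, floor_db)
}

#' Angular diameter of a Goldmann stimulus
#'
#' Goldmann sizes I-V quadruple in area per step, size III being 4 mm^2 at
#' the 300 mm bowl radius; the angular diameter is `2 * atan(r / 300)` with
#' `r` the physical radius, about 0.43 degrees for size III.
#'
#' @param size_label One of `"I"`..`"V"` (or 1..5).
#' @return Angular diameter in degrees.
#' @examples
#' goldmann_diameter("III")   # ~0.431
#' @export
goldmann_diameter <- function(size_label = "III") {
  labels <- c("I", "II", "III", "IV", "V")
  if (is.character(size_label)) {
    n <- match(toupper(size_label), labels)
  } else {
    n <- match(size_label, 1:5)
  }
  if (is.na(n)) stop("unknown Goldmann size label: ", size_label)
  area_mm2 <- 4 * 4^(n - 3)       # size III = 4 mm^2, x4 per step
  r_mm <- sqrt(area_mm2 / pi)
  2 * atan(r_mm / 300) * 180 / pi
}

#' Stimulus specification
#'
#' @param level_db Sensitivity level in dB (displayable range 14-40).
#' @param size Goldmann size label, default `"III"`.
#' @param duration_ms Presentation duration, default 200 ms.
#' @param background_cdm2 Background luminance, default 10 cd/m^2.
#' @return A `svop_stimulus` list with fields `level_db`, `diameter_deg`,
#'   `duration_ms`, `background_cdm2`.
#' @export
stimulus_spec <- function(level_db = 25, size = "III", duration_ms = 200,
                          background_cdm2 = 10) {
  if (level_db < SVOP_LEVEL_RANGE_DB[1] || level_db > SVOP_LEVEL_RANGE_DB[2]) {
    stop("level_db outside displayable range [",
         SVOP_LEVEL_RANGE_DB[1], ", ", SVOP_LEVEL_RANGE_DB[2], "]")
  }
  structure(list(level_db = level_db,
                 diameter_deg = goldmann_diameter(size),
                 duration_ms = duration_ms,
                 background_cdm2 = background_cdm2),
            class = "svop_stimulus")
}

#' Construct a visual-field result
#'
#' Container for one test outcome: per-location threshold estimates in dB
#' plus session metadata.
#'
#' @param pattern An `svop_pattern`.
#' @param threshold_db Numeric vector (length = locations); `NA` for
#'   undetermined points.
#' @param n_presentations Integer vector of presentations per location.
#' @param version Test version: `"v1"`, `"v2"` or `"sap_sim"`.
#' @param complete Logical; a test is complete iff every location has a
#'   threshold.
#' @param duration_s Test duration in seconds (may be `NA`).
#' @param fp_rate For button-response (SAP-like) tests, the observer's
#'   false-positive rate used by the exclusion rules; `NA` otherwise.
#' @param unmeasurable Logical vector: `TRUE` where the staircase bottomed
#'   out at the display floor without a seen response (threshold recorded
#'   as the floor).
#' @return An object of class `svop_field`.
#' @export
visual_field <- function(pattern, threshold_db,
                         n_presentations = rep(0L, nrow(pattern)),
                         version = c("v2", "v1", "sap_sim"),
                         complete = !anyNA(threshold_db),
                         duration_s = NA_real_,
                         fp_rate = NA_real_,
                         unmeasurable = rep(FALSE, nrow(pattern))) {
  version <- match.arg(version)
  stopifnot(length(threshold_db) == nrow(pattern),
            length(n_presentations) == nrow(pattern))
  ok <- is.na(threshold_db) |
    (threshold_db >= SVOP_LEVEL_RANGE_DB[1] & threshold_db <= SVOP_LEVEL_RANGE_DB[2])
  if (!all(ok)) stop("thresholds must lie within [14, 40] dB when present")
  structure(list(
    points = data.frame(
      x_deg = pattern$x_deg, y_deg = pattern$y_deg,
      is_blind_spot = pattern$is_blind_spot,
      threshold_db = threshold_db,
      n_presentations = as.integer(n_presentations),
      unmeasurable = unmeasurable
    ),
    pattern_name = attr(pattern, "pattern_name"),
    eye = attr(pattern, "eye"),
    version = version,
    complete = isTRUE(complete),
    duration_s = duration_s,
    fp_rate = fp_rate
  ), class = "svop_field")
}

#' @export
print.svop_field <- function(x, ...) {
  cat(sprintf("<svop_field> %s %s eye (%s): %d/%d thresholds, %s\n",
              x$pattern_name, x$eye, x$version,
              sum(!is.na(x$points$threshold_db)), nrow(x$points),
              if (x$complete) "complete" else "incomplete"))
  if (!is.na(x$duration_s)) cat(sprintf("  duration: %.0f s\n", x$duration_s))
  invisible(x)
}

#' Pattern accessor for a field result
#' @param field An `svop_field`.
#' @return The `svop_pattern` the field was measured on.
#' @export
field_pattern <- function(field) {
  structure(field$points[c("x_deg", "y_deg", "is_blind_spot")],
            pattern_name = field$pattern_name, eye = field$eye,
            class = c("svop_pattern", "data.frame"))
}
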