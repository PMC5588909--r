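# Gaze-contingent display geometry and the calibrated-panel model.
#
# The screen is a flat panel in the plane z = 0 with its centre at the
# origin, x to the subject's right and y up (mm).  The eye sits at
# (x_mm, y_mm, z_mm) with z_mm > 0 the perpendicular viewing distance.
# Angular positions are expressed as independent horizontal/vertical
# (Fick-style) components: theta_x(p) = atan((p_x - e_x) / e_z) and the
# analogous theta_y.  A stimulus requested at an angular offset from the
# fixated point is placed where these component angles differ from the
# fixation's by exactly the requested offset, so the subtended offset is
# preserved exactly for ANY eye pose -- this is the head-position
# compensation contract.

#' Eye pose relative to the screen
#'
#' @param x_mm,y_mm Lateral / vertical offset of the eye from the screen
#'   centre in mm.
#' @param z_mm Perpendicular viewing distance in mm (> 0); the instrument's
#'   nominal distance is 550 mm.
#' @return An `svop_eye_pose` list.
#' @export
eye_pose <- function(x_mm = 0, y_mm = 0, z_mm = 550) {
  if (!is.finite(z_mm) || z_mm <= 0) stop("z_mm must be > 0")
  structure(list(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm),
            class = "svop_eye_pose")
}

#' Calibrated display model
#'
#' @param width_mm,height_mm Physical panel size; defaults are a 24-inch
#'   16:10 panel (518 x 324 mm).
#' @param background_cdm2 Background luminance (cd/m^2).
#' @param lut Two-column data frame (`grey_level`, `luminance_cdm2`),
#'   strictly increasing in luminance; `NULL` builds a synthetic
#'   gamma-2.2 table whose range covers background through the 14 dB
#'   stimulus ceiling.
#' @param n_grey Number of grey levels for the synthetic table (10-bit
#'   panel by default).
#' @return An `svop_screen` list; `max_cdm2` is the top LUT entry.
#' @export
screen_model <- function(width_mm = 518, height_mm = 324,
                         background_cdm2 = 10, lut = NULL, n_grey = 1024) {
  if (is.null(lut)) {
    # ceiling just above increment(14 dB) + background so the full
    # displayable 40..14 dB range is in gamut
    top <- db_to_increment(14) + background_cdm2
    g <- seq(0, n_grey - 1)
    lut <- data.frame(
      grey_level = g,
      luminance_cdm2 = top * (g / (n_grey - 1))^2.2
    )
  }
  stopifnot(all(c("grey_level", "luminance_cdm2") %in% names(lut)))
  if (any(diff(lut$luminance_cdm2) <= 0)) {
    stop("LUT luminance must be strictly increasing")
  }
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 background_cdm2 = background_cdm2,
                 lut = lut,
                 max_cdm2 = lut$luminance_cdm2[nrow(lut)]),
            class = "svop_screen")
}

# component (Fick) angles of a screen point seen from the eye, degrees
screen_angles <- function(xy_mm, pose) {
  c(atan((xy_mm[1] - pose$x_mm) / pose$z_mm),
    atan((xy_mm[2] - pose$y_mm) / pose$z_mm)) * 180 / pi
}

#' Angular offset subtended between two screen points
#'
#' Component-wise angular offset (degrees) of `xy_mm` relative to
#' `ref_xy_mm`, as seen from `pose`.  Inverse of [project_stimulus()].
#'
#' @param xy_mm,ref_xy_mm Screen points, mm `(x, y)`.
#' @param pose An `svop_eye_pose`.
#' @return Numeric length-2: horizontal and vertical offset in degrees.
#' @export
subtended_offset <- function(xy_mm, ref_xy_mm, pose) {
  screen_angles(xy_mm, pose) - screen_angles(ref_xy_mm, pose)
}

#' Project an angular stimulus offset to screen coordinates
#'
#' Places a stimulus so that its horizontal and vertical angles relative
#' to the currently fixated screen point, measured at the CURRENT eye
#' position, equal the requested visual-field offset.  Because the eye
#' pose enters the projection, stimulus placement continuously compensates
#' for head movement.
#'
#' @param offset_deg Angular offset `(x, y)` in degrees (visual-field frame).
#' @param pose An `svop_eye_pose`.
#' @param fixation_xy_mm Screen point currently fixated, mm.
#' @param screen Optional `svop_screen`; when supplied the projected point
#'   (plus `radius_mm`) must fall on the panel, otherwise `NA` is returned
#'   (off-screen: the location is currently ineligible).
#' @param radius_mm Stimulus radius used for the on-screen check.
#' @return Screen coordinates `(x, y)` in mm, or `c(NA, NA)` if off-screen.
#' @examples
#' project_stimulus(c(10, 0), eye_pose(), c(0, 0))  # ~ (96.98, 0)
#' @export
project_stimulus <- function(offset_deg, pose, fixation_xy_mm,
                             screen = NULL, radius_mm = 0) {
  a <- screen_angles(fixation_xy_mm, pose) + offset_deg
  a_rad <- a * pi / 180
  xy <- c(pose$x_mm + pose$z_mm * tan(a_rad[1]),
          pose$y_mm + pose$z_mm * tan(a_rad[2]))
  if (!is.null(screen)) {
    hw <- screen$width_mm / 2; hh <- screen$height_mm / 2
    if (abs(xy[1]) + radius_mm > hw || abs(xy[2]) + radius_mm > hh) {
      return(c(NA_real_, NA_real_))
    }
  }
  xy
}

#' On-screen stimulus diameter for a requested angular size
#'
#' The drawn diameter subtends `diameter_deg` at the eye at that screen
#' position: `2 * d * tan(diameter_deg / 2)` where `d` is the eye-to-point
#' distance.  Circles are drawn; only the diameter, not the obliquity of
#' the outline, is compensated.
#'
#' @param diameter_deg Angular diameter in degrees.
#' @param pose An `svop_eye_pose`.
#' @param screen_xy_mm Screen position of the stimulus centre, mm.
#' @return Diameter in mm.
#' @examples
#' project_size(goldmann_diameter("III"), eye_pose(), c(0, 0))  # ~4.13 mm
#' @export
project_size <- function(diameter_deg, pose, screen_xy_mm = c(0, 0)) {
  d <- sqrt((screen_xy_mm[1] - pose$x_mm)^2 +
            (screen_xy_mm[2] - pose$y_mm)^2 + pose$z_mm^2)
  2 * d * tan(diameter_deg / 2 * pi / 180)
}

#' Grey level delivering a requested luminance
#'
#' Nearest-neighbour lookup in the calibrated grey-to-luminance table; the
#' delivered error is at most half the local quantisation step.  Requests
#' above the panel ceiling raise a gamut error -- this physical limit is
#' what makes 14 dB the brightest displayable stimulus.
#'
#' @param screen An `svop_screen`.
#' @param luminance_cdm2 Requested luminance (cd/m^2).
#' @return Integer grey level.
#' @export
lut_grey_for_luminance <- function(screen, luminance_cdm2) {
  if (luminance_cdm2 > screen$max_cdm2) {
    stop("requested luminance ", format(luminance_cdm2),
         " cd/m^2 above panel ceiling ", format(screen$max_cdm2),
         " cd/m^2 (out of gamut)")
  }
  lut <- screen$lut
  # luminance is strictly increasing, so the nearest entry brackets the
  # insertion point found by binary search
  i <- findInterval(luminance_cdm2, lut$luminance_cdm2, all.inside = TRUE)
  pick <- if (abs(lut$luminance_cdm2[i + 1] - luminance_cdm2) <
              abs(lut$luminance_cdm2[i] - luminance_cdm2)) i + 1 else i
  lut$grey_level[pick]
}

#' Read / write a display LUT
#'
#' Plain two-column CSV (`grey_level`, `luminance_cdm2`), strictly
#' increasing in luminance.
#'
#' @param path File path.
#' @return `read_lut` returns the LUT data frame.
#' @export
read_lut <- function(path) {
  lut <- utils::read.csv(path)
  if (!all(c("grey_level", "luminance_cdm2") %in% names(lut))) {
    stop("LUT file must have columns grey_level, luminance_cdm2")
  }
  if (any(diff(lut$luminance_cdm2) <= 0)) {
    stop("LUT luminance must be strictly increasing")
  }
  lut
}

#' @rdname read_lut
#' @param lut LUT data frame.
#' @export
write_lut <- function(lut, path) {
  utils::write.csv(lut, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
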