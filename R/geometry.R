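#' Screen geometry for pixel / visual-angle conversion
#'
#' Describes the display and viewing position used during data collection.
#' The defaults are the study setup: a 55.9 cm (22 in.) 1600 x 900 display
#' viewed from 60 cm. Pixel pitch (cm per pixel) is derived from the
#' diagonal and the resolution and is the basis for all conversions between
#' pixels and degrees of visual angle (DVA).
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_cm Physical screen diagonal in centimetres.
#' @param distance_cm Viewing distance in centimetres.
#' @return An object of class `screen_geometry`: a list with the four
#'   fields plus the derived `pitch_cm_px`.
#' @examples
#' geom <- screen_geometry()
#' px_to_dva(1, geom) # ~0.029 DVA per pixel for the default setup
#' @export
screen_geometry <- function(width_px = 1600, height_px = 900,
                            diagonal_cm = 55.9, distance_cm = 60) {
  fields <- c(width_px = width_px, height_px = height_px,
              diagonal_cm = diagonal_cm, distance_cm = distance_cm)
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    gc_abort("All screen geometry fields must be strictly positive.",
             "gc_invalid_geometry")
  }
  pitch <- diagonal_cm / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_cm = diagonal_cm, distance_cm = distance_cm,
         pitch_cm_px = pitch),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f cm diagonal, %.1f cm viewing distance\n",
              x$width_px, x$height_px, x$diagonal_cm, x$distance_cm))
  cat(sprintf("  pixel pitch %.5f cm/px, 1 px = %.5f DVA\n",
              x$pitch_cm_px, px_to_dva(1, x)))
  invisible(x)
}

check_geometry <- function(geometry) {
  if (!inherits(geometry, "screen_geometry")) {
    gc_abort("`geometry` must be a `screen_geometry` object.",
             "gc_invalid_geometry")
  }
  invisible(geometry)
}

#' Convert an on-screen pixel distance to degrees of visual angle
#'
#' Uses the exact chord formula `2 * atan(px * pitch / (2 * distance))`,
#' where pitch is the physical size of one pixel. Monotone in `pixels`;
#' for small extents this is linear at the per-pixel angular resolution of
#' the setup.
#'
#' @param pixels Pixel distance(s), >= 0.
#' @param geometry A [screen_geometry()].
#' @return Angle(s) in degrees of visual angle.
#' @export
px_to_dva <- function(pixels, geometry) {
  check_geometry(geometry)
  if (any(pixels < 0, na.rm = TRUE)) {
    gc_abort("`pixels` must be non-negative.", "gc_invalid_parameter")
  }
  2 * atan(pixels * geometry$pitch_cm_px / (2 * geometry$distance_cm)) * 180 / pi
}

#' Convert degrees of visual angle to an on-screen pixel distance
#'
#' Inverse of [px_to_dva()]; the round trip is exact to floating precision.
#'
#' @param dva Angle(s) in degrees of visual angle, >= 0.
#' @inheritParams px_to_dva
#' @return Pixel distance(s).
#' @export
dva_to_px <- function(dva, geometry) {
  check_geometry(geometry)
  if (any(dva < 0, na.rm = TRUE)) {
    gc_abort("`dva` must be non-negative.", "gc_invalid_parameter")
  }
  2 * geometry$distance_cm * tan(dva * pi / 360) / geometry$pitch_cm_px
}

# Angular resolution at the screen centre, deg per pixel; the correct
# conversion for rates and path lengths, where the chord formula (meant
# for finite extents) does not apply.
dva_per_px <- function(geometry) {
  px_to_dva(1, geometry)
}

# Signed angular screen coordinate relative to an origin (screen centre by
# default); used when differentiating gaze into angular velocity.
px_to_dva_signed <- function(p, origin, geometry) {
  d <- p - origin
  sign(d) * px_to_dva(abs(d), geometry)
}

# Angular separation of two screen points, chord approximation.
angular_distance <- function(x1, y1, x2, y2, geometry) {
  px_to_dva(sqrt((x2 - x1)^2 + (y2 - y1)^2), geometry)
}
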