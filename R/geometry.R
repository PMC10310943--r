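#' Screen geometry for a tablet-based gaze recording setup
#'
#' Describes the physical display used to present the oculomotor tasks and
#' the observer's viewing distance. Defaults correspond to a 12.9-inch
#' tablet (264 ppi, 2732 x 2048 px) viewed at 45 cm with the screen at eye
#' level.
#'
#' @param viewing_distance Eye-to-screen distance in cm (default 45).
#' @param screen_width,screen_height Physical display size in cm.
#' @param pixel_pitch Physical size of one pixel in cm/px.
#'
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' degrees_from_screen(cbind(7.93, 0), geom)
screen_geometry <- function(viewing_distance = 45,
                            screen_width = 26.29,
                            screen_height = 19.71,
                            pixel_pitch = 2.54 / 264) {
  vals <- c(viewing_distance = viewing_distance, screen_width = screen_width,
            screen_height = screen_height, pixel_pitch = pixel_pitch)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen_geometry: all lengths must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %.1f x %.1f cm at %.1f cm viewing distance (%.4f cm/px)\n",
    x$screen_width, x$screen_height, x$viewing_distance, x$pixel_pitch))
  invisible(x)
}

#' Convert on-screen offsets to degrees of visual angle
#'
#' Per-axis conversion using the arctangent model: an offset `d` cm from
#' screen centre at viewing distance `D` subtends `atan(d / D)` on that
#' axis. The screen is assumed at eye level (no obliquity correction).
#' Positive x is rightward, positive y upward.
#'
#' @param offset_cm Numeric 2-column matrix (or length-2 vector) of
#'   horizontal/vertical offsets from screen centre, in cm.
#' @param geometry A [screen_geometry()].
#' @return A 2-column matrix of visual angles in degrees.
#' @export
degrees_from_screen <- function(offset_cm, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  offset_cm <- .as_xy_matrix(offset_cm, "offset_cm")
  atan(offset_cm / geometry$viewing_distance) * 180 / pi
}

#' Convert degrees of visual angle to on-screen offsets
#'
#' Inverse of [degrees_from_screen()]: `tan(theta) * D` per axis.
#'
#' @param angle_deg Numeric 2-column matrix (or length-2 vector) of visual
#'   angles in degrees.
#' @inheritParams degrees_from_screen
#' @return A 2-column matrix of offsets from screen centre in cm.
#' @export
screen_from_degrees <- function(angle_deg, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  angle_deg <- .as_xy_matrix(angle_deg, "angle_deg")
  tan(angle_deg * pi / 180) * geometry$viewing_distance
}

.as_xy_matrix <- function(x, what) {
  if (is.null(dim(x))) {
    if (length(x) != 2) {
      stop(sprintf("%s must be a length-2 vector or a 2-column matrix", what),
           call. = FALSE)
    }
    x <- matrix(x, ncol = 2)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2) {
    stop(sprintf("%s must have exactly 2 columns (x, y)", what), call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  x
}
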