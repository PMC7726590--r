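#' Screen geometry for a bounded 2D response space
#'
#' Defines the rectangular response space of a spatial working-memory task.
#' Coordinates are continuous, with the origin at the top-left corner, x
#' increasing rightward and y increasing downward; the screen is the closed
#' rectangle `[0, width] x [0, height]`, so responses exactly on the boundary
#' are valid. The screen dimensions implicitly set the spatial units of the
#' model (pixels, cm, visual degrees, ...): the uniform guess component has
#' density `1 / (width * height)` per unit area.
#'
#' @param width,height Positive screen extents, in any consistent length unit.
#' @return An object of class `screen_geometry`: a list with elements
#'   `width`, `height` and `area`.
#' @examples
#' scr <- screen_geometry(1366, 768)
#' scr$area  # 1049088
#' @export
screen_geometry <- function(width = 1366, height = 768) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1, is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0)
    stop("screen width and height must be positive")
  structure(list(width = width, height = height, area = width * height),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g (area %g)\n", x$width, x$height,
              x$area))
  invisible(x)
}

as_screen <- function(screen) {
  if (inherits(screen, "screen_geometry")) return(screen)
  if (is.numeric(screen) && length(screen) == 2)
    return(screen_geometry(screen[1], screen[2]))
  stop("`screen` must be a screen_geometry or a numeric length-2 vector")
}

#' Convert between pixels, centimetres and visual degrees
#'
#' Conversions assume a flat screen viewed perpendicularly, so a visual angle
#' `a` subtends `distance * tan(a)` centimetres. Defaults correspond to a
#' typical desktop set-up of a 40 cm viewing distance at 42 px/cm, under
#' which 1 visual degree is about 29.3 px and 3 degrees about 88 px.
#'
#' @param px,cm,degrees Quantity to convert (vectorised).
#' @param distance Viewing distance in cm.
#' @param px_per_cm Screen resolution in pixels per cm.
#' @return Converted numeric vector.
#' @examples
#' degrees_to_px(3)    # ~88 px
#' degrees_to_px(1.5)  # ~44 px, the fixed swap-error threshold
#' @name units
NULL

#' @rdname units
#' @export
degrees_to_px <- function(degrees, distance = 40, px_per_cm = 42) {
  tan(degrees * pi / 180) * distance * px_per_cm
}

#' @rdname units
#' @export
px_to_degrees <- function(px, distance = 40, px_per_cm = 42) {
  atan2(px / px_per_cm, distance) * 180 / pi
}

#' @rdname units
#' @export
px_to_cm <- function(px, px_per_cm = 42) px / px_per_cm

#' @rdname units
#' @export
cm_to_px <- function(cm, px_per_cm = 42) cm * px_per_cm

## clip an n x 2 coordinate matrix to the closed screen rectangle
clip_to_screen <- function(points, screen) {
  screen <- as_screen(screen)
  points[, 1] <- pmin(pmax(points[, 1], 0), screen$width)
  points[, 2] <- pmin(pmax(points[, 2], 0), screen$height)
  points
}

on_screen <- function(points, screen) {
  screen <- as_screen(screen)
  points[, 1] >= 0 & points[, 1] <= screen$width &
    points[, 2] >= 0 & points[, 2] <= screen$height
}
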