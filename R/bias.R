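#' Response-bias transforms
#'
#' Parametric distortions of response locations, usable both generatively
#' (applied to simulated responses, followed by clipping to the screen) and
#' as fitted corrections (applied to the mixture-component means before the
#' density is evaluated).
#'
#' * `apply_constant_bias()` subtracts a fixed translation: `point - bias`,
#'   edge-constrained (clipped) to the screen rectangle.
#' * `apply_edge_proportional_bias()` shifts each response by a proportion
#'   `b` of its distance to the named edge, along that axis only (responses
#'   do not move along the other axis); positive `b` moves toward the edge,
#'   negative away.
#' * `apply_radial_bias()` moves responses a proportion `b` of the way
#'   toward a centre (`point + b * (center - point)`): positive `b`
#'   contracts toward the centre, negative expands away; results are
#'   clipped to the screen. With a per-trial centre equal to the nontarget
#'   location this reproduces a nontarget "pull" on responses, which is
#'   distinguishable from misbinding (responses land between target and
#'   nontarget rather than on the nontarget).
#'
#' All transforms with parameter zero are the identity.
#'
#' @param points An `n x 2` matrix (or length-2 vector) of coordinates.
#' @param bias Length-2 constant translation `c(bx, by)`.
#' @param b Proportional bias in `(-1, 1]`.
#' @param edge `"right"`, `"left"`, `"top"` or `"bottom"`.
#' @param center Length-2 point, or an `n x 2` matrix of per-trial centres.
#' @param screen A [screen_geometry()].
#' @return Matrix of transformed coordinates, clipped to the screen.
#' @examples
#' scr <- screen_geometry(1366, 768)
#' apply_constant_bias(c(500, 400), c(20, 0), scr)          # (480, 400)
#' apply_edge_proportional_bias(c(1000, 400), 0.5, "right", scr)  # x' = 1183
#' @export
apply_constant_bias <- function(points, bias, screen) {
  points <- coerce_points(points)
  points[, 1] <- points[, 1] - bias[1]
  points[, 2] <- points[, 2] - bias[2]
  clip_to_screen(points, screen)
}

#' @rdname apply_constant_bias
#' @export
apply_edge_proportional_bias <- function(points, b,
                                         edge = c("right", "left", "top",
                                                  "bottom"),
                                         screen) {
  edge <- match.arg(edge)
  points <- coerce_points(points)
  screen <- as_screen(screen)
  switch(edge,
    right  = points[, 1] <- points[, 1] + b * (screen$width - points[, 1]),
    left   = points[, 1] <- points[, 1] - b * points[, 1],
    bottom = points[, 2] <- points[, 2] + b * (screen$height - points[, 2]),
    top    = points[, 2] <- points[, 2] - b * points[, 2])
  clip_to_screen(points, screen)
}

#' @rdname apply_constant_bias
#' @export
apply_radial_bias <- function(points, b, center, screen) {
  points <- coerce_points(points)
  if (is.null(dim(center))) center <- matrix(center, nrow(points), 2,
                                             byrow = TRUE)
  points <- points + b * (center - points)
  clip_to_screen(points, screen)
}

coerce_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  as.matrix(points)
}

## Resolve the bias centre spec of a model into per-trial coordinates.
resolve_bias_center <- function(model, tm, screen) {
  if (model$bias != "radial") return(NULL)
  spec <- model$bias_center
  if (is.numeric(spec) && length(spec) == 2)
    return(matrix(spec, tm$n, 2, byrow = TRUE))
  if (identical(spec, "screen_center"))
    return(matrix(c(screen$width / 2, screen$height / 2), tm$n, 2,
                  byrow = TRUE))
  if (identical(spec, "nontarget")) {
    if (ncol(tm$ntx) == 0 || any(tm$m < 1))
      stop("radial nontarget bias requires a nontarget on every trial")
    if (any(tm$m > 1))
      stop("radial nontarget bias is only defined for one nontarget per trial")
    return(cbind(tm$ntx[, 1], tm$nty[, 1]))
  }
  stop("unknown bias centre specification: ", deparse(spec))
}

## Apply the model's bias transform to component means during fitting.
shift_means <- function(means, model, bias, screen, centers = NULL) {
  switch(model$bias,
    none = means,
    constant = apply_constant_bias(means, c(bias[["bias_x"]],
                                            bias[["bias_y"]]), screen),
    edge = apply_edge_proportional_bias(means, bias[["bias_prop"]],
                                        model$edge, screen),
    radial = apply_radial_bias(means, bias[["bias_prop"]], centers, screen))
}

## Apply the model's bias transform to simulated responses (then clip).
apply_bias_to_responses <- function(resp, model, bias, screen,
                                    centers = NULL) {
  shift_means(resp, model, bias, screen, centers)
}
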