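#' Response-sampling guess distribution (2D kernel density estimate)
#'
#' Builds a product-Gaussian kernel density estimate over a participant's
#' response locations, for use as the guessing component of a mixture model
#' in place of the uniform distribution. Guesses drawn from a random other
#' trial are unrelated to the current trial's stimuli but carry the
#' participant's own response biases, so this "response sampling" density
#' often explains guesses better than uniform.
#'
#' The default per-axis bandwidth follows Scott's rule for d = 2:
#' `h_j = sd_j * n^(-1/6)`. Because kernel mass can fall off-screen, the
#' density is renormalised over the screen rectangle (analytically, since
#' the kernels are axis-aligned Gaussians), keeping gamma interpretable as
#' a probability.
#'
#' @param responses An `n x 2` matrix (or data frame with `resp_x`,
#'   `resp_y`) of response locations; `n >= 2` with nonzero spread on both
#'   axes.
#' @param bandwidth Optional length-2 override of the per-axis bandwidths.
#' @param screen A [screen_geometry()].
#' @param normalize Renormalise over the screen (default `TRUE`).
#' @return An object of class `response_kde`.
#' @export
build_response_kde <- function(responses, bandwidth = NULL,
                               screen = screen_geometry(),
                               normalize = TRUE) {
  screen <- as_screen(screen)
  if (is.data.frame(responses))
    responses <- cbind(responses$resp_x, responses$resp_y)
  responses <- coerce_points(responses)
  n <- nrow(responses)
  if (n < 2) stop("at least 2 responses are needed to build a response KDE")
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::sd(responses[, 1]),
                   stats::sd(responses[, 2])) * n^(-1 / 6)
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("zero or non-finite bandwidth (identical responses?); ",
         "supply `bandwidth` explicitly")
  obj <- structure(list(x = responses[, 1], y = responses[, 2],
                        h = bandwidth, screen = screen,
                        norm_const = 1, normalized = normalize),
                   class = "response_kde")
  if (normalize) {
    ## mean on-screen mass of the kernels (product of axis-wise masses)
    mx <- stats::pnorm((screen$width - obj$x) / bandwidth[1]) -
      stats::pnorm(-obj$x / bandwidth[1])
    my <- stats::pnorm((screen$height - obj$y) / bandwidth[2]) -
      stats::pnorm(-obj$y / bandwidth[2])
    obj$norm_const <- mean(mx * my)
  }
  obj
}

#' @export
print.response_kde <- function(x, ...) {
  cat(sprintf("<response_kde> %d responses, bandwidth (%.3g, %.3g)%s\n",
              length(x$x), x$h[1], x$h[2],
              if (x$normalized) ", screen-normalised" else ""))
  invisible(x)
}

#' Evaluate a response KDE
#'
#' @param kde A [build_response_kde()] object.
#' @param points An `n x 2` matrix of evaluation points.
#' @return Density per unit area at each point.
#' @export
kde_density <- function(kde, points) {
  points <- coerce_points(points)
  dx <- outer(points[, 1], kde$x, "-") / kde$h[1]
  dy <- outer(points[, 2], kde$y, "-") / kde$h[2]
  k <- exp(-0.5 * (dx^2 + dy^2)) / (2 * pi * kde$h[1] * kde$h[2])
  rowMeans(k) / kde$norm_const
}

## sample n points from the KDE, resampled until on-screen
kde_sample <- function(kde, n) {
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  while (length(todo)) {
    i <- sample.int(length(kde$x), length(todo), replace = TRUE)
    cand <- cbind(kde$x[i] + stats::rnorm(length(todo), 0, kde$h[1]),
                  kde$y[i] + stats::rnorm(length(todo), 0, kde$h[2]))
    ok <- on_screen(cand, kde$screen)
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out
}

#' Attach a KDE guess distribution to a model
#'
#' Returns a copy of `model` whose guessing component density `gamma / A`
#' is replaced by `gamma * kde(response)`. The free-parameter count is
#' unchanged (the KDE is built from data, not fitted).
#'
#' @param model A [wm_model()].
#' @param kde A [build_response_kde()] object.
#' @export
kde_guess_model <- function(model, kde) {
  stopifnot(inherits(model, "wm_model"), inherits(kde, "response_kde"))
  if (model$dim != 2) stop("KDE guesses are only defined for 2D models")
  model$guess <- "kde"
  model$kde <- kde
  model
}
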