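#' Define a mixture model variant
#'
#' Assembles a model definition: which mixture family (2D bivariate Gaussian
#' or 1D von Mises; with or without the misbinding component; optionally
#' with two nontarget classes carrying separate misbinding weights), which
#' guess distribution (uniform over the screen, or a response-sampling KDE),
#' which response-bias transform is fitted alongside the mixture weights,
#' and whether the continuous-report likelihood renormalises the Gaussian
#' components for screen truncation.
#'
#' Free parameters (the count `k` used in the BIC):
#' \describe{
#'   \item{misbind2d}{`beta`, `gamma`, `sigma` (k = 3)}
#'   \item{standard2d}{`gamma`, `sigma` (k = 2)}
#'   \item{misbind2class}{`beta1`, `beta2`, `gamma`, `sigma` (k = 4)}
#'   \item{misbind1d}{`beta`, `gamma`, `kappa` (k = 3)}
#'   \item{standard1d}{`gamma`, `kappa` (k = 2)}
#'   \item{standard2afc}{`gamma`, `sigma` (k = 2), change-detection likelihood}
#'   \item{misbind2afc}{`beta`, `gamma`, `sigma` (k = 3), change-detection
#'     likelihood (slow: the probe integral involves every nontarget)}
#' }
#' A constant bias adds 2 free parameters (`bias_x`, `bias_y`); edge and
#' radial biases add 1 (`bias_prop`). The KDE guess adds none.
#'
#' @param type Model family; see Details.
#' @param bias One of `"none"`, `"constant"`, `"edge"`, `"radial"`.
#' @param bias_center For radial biases: `"screen_center"`, `"nontarget"`
#'   (per-trial first nontarget; requires exactly one nontarget per trial),
#'   or a fixed `c(x, y)`.
#' @param edge For edge-proportional biases: which edge responses shift
#'   toward (`"right"`, `"left"`, `"top"`, `"bottom"`).
#' @param guess `"uniform"` or `"kde"`; a KDE guess requires `kde`.
#' @param kde A [build_response_kde()] object, when `guess = "kde"`.
#' @param truncated If `TRUE`, Gaussian components are renormalised by their
#'   on-screen mass (analytic, since covariance is zero), so the mixture
#'   density integrates to 1 over the screen. The default `FALSE` evaluates
#'   plain Gaussians, matching common practice for these models.
#' @return An object of class `wm_model`.
#' @examples
#' wm_model("misbind2d")
#' wm_model("standard2d", bias = "radial", bias_center = "screen_center")
#' @export
wm_model <- function(type = c("misbind2d", "standard2d", "misbind2class",
                              "misbind1d", "standard1d",
                              "standard2afc", "misbind2afc"),
                     bias = c("none", "constant", "edge", "radial"),
                     bias_center = "screen_center",
                     edge = c("right", "left", "top", "bottom"),
                     guess = c("uniform", "kde"),
                     kde = NULL,
                     truncated = FALSE) {
  type <- match.arg(type)
  bias <- match.arg(bias)
  edge <- match.arg(edge)
  guess <- match.arg(guess)
  dim <- if (type %in% c("misbind1d", "standard1d")) 1L else 2L
  response <- if (grepl("2afc", type)) "2afc" else "continuous"
  if (dim == 1 && (bias != "none" || guess != "uniform"))
    stop("bias transforms and KDE guesses are only defined for 2D models")
  if (guess == "kde" && is.null(kde))
    stop("`guess = \"kde\"` requires a `kde` object; see build_response_kde()")
  free <- switch(type,
    misbind2d    = c("beta", "gamma", "sigma"),
    standard2d   = c("gamma", "sigma"),
    misbind2class = c("beta1", "beta2", "gamma", "sigma"),
    misbind1d    = c("beta", "gamma", "kappa"),
    standard1d   = c("gamma", "kappa"),
    standard2afc = c("gamma", "sigma"),
    misbind2afc  = c("beta", "gamma", "sigma"))
  free <- c(free, switch(bias, none = character(0),
                         constant = c("bias_x", "bias_y"),
                         edge = "bias_prop", radial = "bias_prop"))
  structure(list(type = type, dim = dim, response = response,
                 misbinding = grepl("misbind", type),
                 two_class = type == "misbind2class",
                 bias = bias, bias_center = bias_center, edge = edge,
                 guess = guess, kde = kde, truncated = truncated,
                 free_params = free, k = length(free)),
            class = "wm_model")
}

#' @export
print.wm_model <- function(x, ...) {
  cat(sprintf("<wm_model> %s (%dD, %s)\n", x$type, x$dim, x$response))
  cat("  free parameters:", paste(x$free_params, collapse = ", "),
      sprintf("(k = %d)\n", x$k))
  if (x$bias != "none") cat("  bias:", x$bias, "\n")
  if (x$guess != "uniform") cat("  guess distribution: response-sampling KDE\n")
  if (x$truncated) cat("  screen-truncation renormalisation: on\n")
  invisible(x)
}

## ---- transforms between natural and unconstrained optimisation space ----
## Mixture weights use an additive log-ratio transform relative to alpha so
## the simplex constraint beta + gamma <= 1 is honoured without a
## constrained optimiser; sigma/kappa are fitted on the log scale; the
## proportional bias uses atanh so |b| < 1.

SIGMA_MIN <- 1e-2

model_bounds <- function(model, screen = NULL) {
  smax <- if (!is.null(screen)) max(screen$width, screen$height) else 1e4
  list(sigma = c(SIGMA_MIN, smax), kappa = c(1e-4, 1e4))
}

par_to_unconstrained <- function(par, model) {
  u <- numeric(0)
  eps <- 1e-6
  clamp01 <- function(p) pmin(pmax(p, eps), 1 - eps)
  if (model$two_class) {
    b1 <- clamp01(par$beta1); b2 <- clamp01(par$beta2); g <- clamp01(par$gamma)
    a <- max(1 - b1 - b2 - g, eps)
    u <- c(u, log(b1 / a), log(b2 / a), log(g / a))
  } else if (model$misbinding) {
    b <- clamp01(par$beta); g <- clamp01(par$gamma)
    a <- max(1 - b - g, eps)
    u <- c(u, log(b / a), log(g / a))
  } else {
    g <- clamp01(par$gamma)
    u <- c(u, log(g / (1 - g)))
  }
  u <- c(u, if (model$dim == 2) log(par$sigma) else log(par$kappa))
  if (model$bias == "constant") {
    b <- if (is.null(par$bias)) c(0, 0)
    else c(par$bias[["bias_x"]], par$bias[["bias_y"]])
    u <- c(u, b)
  } else if (model$bias %in% c("edge", "radial")) {
    b <- if (is.null(par$bias)) 0 else par$bias[["bias_prop"]]
    u <- c(u, atanh(min(max(b, -1 + eps), 1 - eps)))
  }
  u
}

unconstrained_to_par <- function(u, model, screen = NULL) {
  bounds <- model_bounds(model, screen)
  i <- 1
  if (model$two_class) {
    e <- exp(pmin(u[1:3], 30)); s <- 1 + sum(e)
    b1 <- e[1] / s; b2 <- e[2] / s; g <- e[3] / s
    i <- 4
    w <- list(beta1 = b1, beta2 = b2, gamma = g)
  } else if (model$misbinding) {
    e <- exp(pmin(u[1:2], 30)); s <- 1 + sum(e)
    w <- list(beta = e[1] / s, gamma = e[2] / s)
    i <- 3
  } else {
    w <- list(beta = 0, gamma = stats::plogis(u[1]))
    i <- 2
  }
  if (model$dim == 2) {
    w$sigma <- min(max(exp(u[i]), bounds$sigma[1]), bounds$sigma[2])
  } else {
    w$kappa <- min(max(exp(u[i]), bounds$kappa[1]), bounds$kappa[2])
  }
  i <- i + 1
  bias <- NULL
  if (model$bias == "constant") {
    bias <- c(bias_x = u[i], bias_y = u[i + 1])
  } else if (model$bias %in% c("edge", "radial")) {
    bias <- c(bias_prop = tanh(u[i]))
  }
  w$bias <- bias
  do.call(mixture_params, w)
}

## flatten a mixture_params into the model's natural free-parameter vector
par_to_natural <- function(par, model) {
  out <- vapply(model$free_params, function(nm) {
    if (nm %in% c("bias_x", "bias_y", "bias_prop")) par$bias[[nm]]
    else par[[nm]]
  }, numeric(1))
  names(out) <- model$free_params
  out
}

natural_to_par <- function(x, model) {
  x <- as.list(x)
  bias_names <- intersect(names(x), c("bias_x", "bias_y", "bias_prop"))
  bias <- if (length(bias_names)) unlist(x[bias_names]) else NULL
  args <- x[setdiff(names(x), bias_names)]
  args$bias <- bias
  do.call(mixture_params, args)
}
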