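## Core mixture densities and log-likelihoods.
##
## The three-component model explains a continuous-report response as
## target responding (alpha), misbinding to a nontarget (beta) or guessing
## (gamma), with alpha + beta + gamma = 1. In 2D the component error
## distribution is an isotropic bivariate Gaussian (SD sigma per axis, zero
## covariance) and guesses are uniform over the screen area A; in 1D it is
## the von Mises distribution (concentration kappa) and guesses are uniform
## over the circle.

## isotropic bivariate normal density as a function of squared distance
gauss2_sqd <- function(d2, sigma) {
  exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
}

## on-screen probability mass of an isotropic Gaussian centred at `center`
## (n x 2). Analytic because the covariance is zero.
gauss2_screen_mass <- function(center, sigma, screen) {
  px <- stats::pnorm((screen$width - center[, 1]) / sigma) -
    stats::pnorm(-center[, 1] / sigma)
  py <- stats::pnorm((screen$height - center[, 2]) / sigma) -
    stats::pnorm(-center[, 2] / sigma)
  px * py
}

## von Mises density, numerically stable for large kappa
vonmises_density <- function(delta, kappa) {
  if (kappa < 1e-12) return(rep(1 / (2 * pi), length(delta)))
  exp(kappa * (cos(delta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Continuous-report mixture densities
#'
#' `density_2d()` evaluates the 2D misbinding-model response density
#' `alpha * psi_sigma(resp - targ) + beta * mean_i psi_sigma(resp - nt_i)
#' + gamma / A` per trial, where `psi_sigma` is the isotropic bivariate
#' Gaussian and `A` the screen area. `density_1d()` is the circular
#' analogue with von Mises components and a `gamma / (2*pi)` guess term.
#' `density_2d_two_class()` splits the misbinding weight into `beta1` and
#' `beta2` for nontargets labelled class 1 and 2 (e.g. the nonprobed test
#' item versus distractors).
#'
#' Trials without nontargets contribute no misbinding term; if `beta > 0`
#' on such trials the remaining weights are used as given (the density then
#' integrates to less than one on those trials) and a warning is raised
#' once per call. The same rule applies per class in the two-class model.
#'
#' @param data Trial data frame (see [trial-data]).
#' @param params A [mixture_params()].
#' @param screen A [screen_geometry()].
#' @param truncated If `TRUE`, renormalise each Gaussian component by its
#'   on-screen mass so the density integrates to 1 over the screen.
#' @return Numeric vector of per-trial densities (per unit area in 2D, per
#'   radian in 1D).
#' @examples
#' scr <- screen_geometry(1366, 768)
#' d <- data.frame(resp_x = 500, resp_y = 400, targ_x = 500, targ_y = 400)
#' density_2d(d, mixture_params(gamma = 1, sigma = 30), scr)  # 1 / A
#' @export
density_2d <- function(data, params, screen, truncated = FALSE) {
  params <- as_mixture_params(params)
  if (is.null(params$sigma)) stop("2D densities require `sigma`")
  mixture_density(data, params, wm_model("misbind2d", truncated = truncated),
                  as_screen(screen))
}

#' @rdname density_2d
#' @export
density_1d <- function(data, params) {
  params <- as_mixture_params(params)
  if (is.null(params$kappa)) stop("1D densities require `kappa`")
  mixture_density(data, params, wm_model("misbind1d"), NULL)
}

#' @rdname density_2d
#' @export
density_2d_two_class <- function(data, params, screen, truncated = FALSE) {
  params <- as_mixture_params(params)
  if (is.null(params$beta1))
    stop("two-class densities require `beta1` and `beta2`")
  mixture_density(data, params, wm_model("misbind2class",
                                         truncated = truncated),
                  as_screen(screen))
}

## General per-trial mixture density for any wm_model. `tm` may carry
## precomputed trial matrices to avoid re-extraction inside optimisation.
mixture_density <- function(data, params, model, screen, tm = NULL) {
  params <- as_mixture_params(params)
  if (model$dim == 1) {
    if (is.null(tm)) tm <- trial_matrices_1d(data)
    if (any(!is.finite(tm$resp)) || any(!is.finite(tm$targ)))
      stop("non-finite response or target angles")
    kappa <- params$kappa
    dens <- params$alpha * vonmises_density(tm$resp - tm$targ, kappa)
    if (ncol(tm$nt)) {
      nt_d <- vonmises_density(tm$resp - tm$nt, kappa)
      dim(nt_d) <- dim(tm$nt)
      nt_d[is.na(tm$nt)] <- 0
      nt_mean <- rowSums(nt_d) / pmax(tm$m, 1)
    } else nt_mean <- 0
    if (params$beta > 0 && any(tm$m == 0))
      warning("beta > 0 but ", sum(tm$m == 0),
              " trial(s) have no nontargets; misbinding term dropped there")
    dens <- dens + params$beta * nt_mean + params$gamma / (2 * pi)
    return(dens)
  }

  if (is.null(tm)) tm <- trial_matrices(data)
  if (any(!is.finite(tm$resp)) || any(!is.finite(tm$targ)))
    stop("non-finite response or target coordinates")
  sigma <- params$sigma
  targ <- tm$targ
  ntx <- tm$ntx; nty <- tm$nty

  if (model$bias != "none" && !is.null(params$bias)) {
    centers <- resolve_bias_center(model, tm, screen)
    targ <- shift_means(targ, model, params$bias, screen, centers)
    if (ncol(ntx)) {
      for (j in seq_len(ncol(ntx))) {
        sh <- shift_means(cbind(ntx[, j], nty[, j]), model, params$bias,
                          screen, centers)
        ntx[, j] <- sh[, 1]; nty[, j] <- sh[, 2]
      }
    }
  }

  d2t <- (tm$resp[, 1] - targ[, 1])^2 + (tm$resp[, 2] - targ[, 2])^2
  targ_dens <- gauss2_sqd(d2t, sigma)
  if (model$truncated)
    targ_dens <- targ_dens / gauss2_screen_mass(targ, sigma, screen)

  nt_dens <- NULL
  if (ncol(ntx)) {
    d2 <- (ntx - tm$resp[, 1])^2 + (nty - tm$resp[, 2])^2
    nt_dens <- gauss2_sqd(d2, sigma)
    if (model$truncated) {
      for (j in seq_len(ncol(ntx))) {
        mass <- gauss2_screen_mass(cbind(ntx[, j], nty[, j]), sigma, screen)
        nt_dens[, j] <- nt_dens[, j] / mass
      }
    }
    nt_dens[is.na(d2)] <- 0
  }

  guess_dens <- if (model$guess == "kde")
    kde_density(model$kde, tm$resp)
  else rep(1 / screen$area, tm$n)

  if (model$two_class) {
    cls <- tm$class
    if (ncol(cls) == 0 || all(is.na(cls)))
      stop("two-class model requires nt{i}_class labels")
    in1 <- !is.na(cls) & cls == 1 & !is.na(ntx)
    in2 <- !is.na(cls) & cls == 2 & !is.na(ntx)
    m1 <- rowSums(in1); m2 <- rowSums(in2)
    s1 <- rowSums(nt_dens * in1) / pmax(m1, 1)
    s2 <- rowSums(nt_dens * in2) / pmax(m2, 1)
    if ((params$beta1 > 0 && any(m1 == 0)) ||
        (params$beta2 > 0 && any(m2 == 0)))
      warning("some trials lack nontargets of a class with positive weight; ",
              "that misbinding term contributes 0 there")
    dens <- params$alpha * targ_dens + params$beta1 * s1 +
      params$beta2 * s2 + params$gamma * guess_dens
  } else {
    nt_mean <- if (is.null(nt_dens)) 0
    else rowSums(nt_dens) / pmax(tm$m, 1)
    if (params$beta > 0 && any(tm$m == 0))
      warning("beta > 0 but ", sum(tm$m == 0),
              " trial(s) have no nontargets; misbinding term dropped there")
    dens <- params$alpha * targ_dens + params$beta * nt_mean +
      params$gamma * guess_dens
  }
  dens
}

#' Dataset log-likelihood
#'
#' Sums the log of the per-trial mixture density over all trials, honouring
#' per-trial nontarget sets. Returns `-Inf` (with a warning naming the
#' offending trials) if any trial has non-positive density.
#'
#' @inheritParams density_2d
#' @param model A [wm_model()]; defaults to the plain 2D misbinding model.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, params, model = wm_model("misbind2d"),
                           screen = screen_geometry()) {
  screen <- if (model$dim == 2) as_screen(screen) else NULL
  dens <- mixture_density(data, params, model, screen)
  if (any(dens <= 0 | !is.finite(dens))) {
    warning("non-positive density on trial(s) ",
            paste(utils::head(which(dens <= 0 | !is.finite(dens)), 5),
                  collapse = ", "), "; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(log(dens))
}

#' Bayesian information criterion
#'
#' `k * log(n) - 2 * loglik`; smaller values indicate preferred models.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of trials.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}

#' Convert von Mises concentration to circular standard deviation
#'
#' Uses the circular SD `sqrt(-2 * log(I1(kappa) / I0(kappa)))`, in radians.
#' The output is capped at the SD of the circular uniform distribution,
#' `sqrt(pi^2 / 3)` (~103.9 degrees), so that near-zero concentrations map
#' to a finite, plottable value; `sd_to_kappa()` inverts the (uncapped)
#' formula numerically.
#'
#' @param kappa Non-negative concentration(s).
#' @param sd Circular SD in radians, below the uniform cap.
#' @return `kappa_to_sd()`: circular SD in radians; `sd_to_kappa()`: kappa.
#' @examples
#' kappa_to_sd(2)
#' sd_to_kappa(kappa_to_sd(2))
#' @export
kappa_to_sd <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be non-negative")
  cap <- sqrt(pi^2 / 3)
  out <- vapply(kappa, function(k) {
    if (k < 1e-10) return(cap)
    r <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    if (r <= 0) return(cap)
    min(sqrt(-2 * log(r)), cap)
  }, numeric(1))
  out
}

#' @rdname kappa_to_sd
#' @export
sd_to_kappa <- function(sd) {
  cap <- sqrt(pi^2 / 3)
  vapply(sd, function(s) {
    stopifnot(s > 0)
    if (s >= cap) return(0)
    f <- function(logk) {
      k <- exp(logk)
      ## asymptotic ratio for very large kappa, where besselI underflows
      r <- if (k > 1e5) 1 - 1 / (2 * k)
      else besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
      sqrt(-2 * log(r)) - s
    }
    exp(stats::uniroot(f, c(log(1e-8), log(1e8)), tol = 1e-12)$root)
  }, numeric(1))
}
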