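#' Maximum-likelihood model fitting
#'
#' Fits a mixture model by maximising the dataset log-likelihood over the
#' model's free parameters. The simplex constraint on the mixing weights
#' (`beta, gamma >= 0`, `beta + gamma <= 1`) is honoured by optimising an
#' additive log-ratio transform of the weights; `sigma`/`kappa` are
#' optimised on the log scale with bounds `sigma` in
#' `[0.01, max(width, height)]`. A coarse multi-start grid over the
#' transformed mixture parameters plus one method-of-moments start is
#' evaluated, and Nelder-Mead refinement is run from the best
#' `n_refine` start points; the best refined optimum is returned.
#'
#' @param data Trial data frame (continuous report, 1D or 2D per the
#'   model), or change-detection data for 2AFC models.
#' @param model A [wm_model()].
#' @param screen A [screen_geometry()] (ignored for 1D models).
#' @param n_refine Number of start points refined with the optimiser.
#' @param hessian If `TRUE`, also compute the Hessian-based covariance of
#'   the natural free parameters (used by [condition_compare()]).
#' @param control Optimiser control overrides; defaults use a relative
#'   objective tolerance of 1e-8 and up to 500 iterations.
#' @return An object of class `wm_fit`: point estimates (`params`), the
#'   maximised `loglik`, `bic`, free-parameter count `k`, trial count `n`,
#'   `convergence` flag, `n_starts`, and optionally `vcov`.
#' @examples
#' \donttest{
#' set.seed(1)
#' d <- simulate_responses(mixture_params(beta = .3, gamma = .3, sigma = 30))
#' fit_mle(d, wm_model("misbind2d"))
#' }
#' @export
fit_mle <- function(data, model = wm_model("misbind2d"),
                    screen = screen_geometry(), n_refine = 3,
                    hessian = FALSE, control = list()) {
  stopifnot(inherits(model, "wm_model"))
  screen <- if (model$dim == 2) as_screen(screen) else NULL
  n <- nrow(data)
  if (n < model$k + 1)
    stop("need at least k + 1 = ", model$k + 1, " trials to fit this model")
  negll <- build_negloglik(data, model, screen)

  starts <- start_points(data, model, screen)
  vals <- vapply(starts, negll, numeric(1))
  ord <- order(vals)
  top <- ord[seq_len(min(n_refine, length(ord)))]
  ctrl <- utils::modifyList(list(reltol = 1e-8, maxit = 500), control)

  best <- NULL
  any_conv <- FALSE
  diagnostics <- character(0)
  for (i in top) {
    opt <- tryCatch(
      stats::optim(starts[[i]], negll, method = "Nelder-Mead",
                   control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) {
      diagnostics <- c(diagnostics, sprintf("start %d: optimiser error", i))
      next
    }
    any_conv <- any_conv || opt$convergence == 0
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimisation starts failed:\n",
         paste(diagnostics, collapse = "\n"))

  params <- unconstrained_to_par(best$par, model, screen)
  loglik <- -best$value
  fit <- structure(list(params = params, loglik = loglik,
                        bic = bic(loglik, model$k, n), k = model$k, n = n,
                        model = model, screen = screen,
                        convergence = any_conv && best$convergence == 0,
                        n_starts = length(starts), vcov = NULL),
                   class = "wm_fit")
  if (hessian) fit$vcov <- fit_vcov(fit, data)
  fit
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf("<wm_fit> %s: lnL = %.3f, BIC = %.3f (k = %d, n = %d)%s\n",
              x$model$type, x$loglik, x$bic, x$k, x$n,
              if (!x$convergence) " [not converged]" else ""))
  print(x$params)
  invisible(x)
}

build_negloglik <- function(data, model, screen) {
  if (model$response == "2afc") {
    tm <- cd_matrices(data)
    tm$areas <- vapply(seq_len(tm$n), function(i)
      disc_rect_area(tm$targ[i, ], tm$d[i], screen), numeric(1))
    return(function(u) {
      par <- unconstrained_to_par(u, model, screen)
      ll <- loglik_2afc_tm(tm, par, model, screen)
      if (!is.finite(ll)) 1e10 else -ll
    })
  }
  tm <- if (model$dim == 2) trial_matrices(data) else trial_matrices_1d(data)
  if (model$misbinding && !model$two_class && any(tm$m == 0))
    warning("dataset contains trials without nontargets; the misbinding ",
            "component is dropped on those trials")
  plain <- model$bias == "none" && model$guess == "uniform" &&
    !model$two_class && !model$truncated
  if (plain && model$dim == 2)
    return(negloglik_plain_2d(tm, model, screen))
  if (plain && model$dim == 1)
    return(negloglik_plain_1d(tm, model))
  function(u) {
    par <- unconstrained_to_par(u, model, screen)
    dens <- suppressWarnings(mixture_density(data, par, model, screen, tm))
    if (any(dens <= 0 | !is.finite(dens))) return(1e10)
    -sum(log(dens))
  }
}

## Specialised objective for the plain 2D models: squared distances are
## precomputed once, so each evaluation is a handful of vectorised ops.
negloglik_plain_2d <- function(tm, model, screen) {
  d2t <- (tm$resp[, 1] - tm$targ[, 1])^2 + (tm$resp[, 2] - tm$targ[, 2])^2
  has_nt <- ncol(tm$ntx) > 0
  if (has_nt) {
    d2nt <- (tm$ntx - tm$resp[, 1])^2 + (tm$nty - tm$resp[, 2])^2
    nt_na <- is.na(d2nt)
    minv <- 1 / pmax(tm$m, 1)
  }
  inv_area <- 1 / screen$area
  misbind <- model$misbinding
  smax <- max(screen$width, screen$height)
  function(u) {
    if (misbind) {
      e1 <- exp(min(u[1], 30)); e2 <- exp(min(u[2], 30))
      s <- 1 + e1 + e2
      beta <- e1 / s; gamma <- e2 / s; alpha <- 1 / s
      sigma <- exp(u[3])
    } else {
      gamma <- stats::plogis(u[1]); beta <- 0; alpha <- 1 - gamma
      sigma <- exp(u[2])
    }
    if (sigma < SIGMA_MIN || sigma > smax) return(1e10)
    inv2s2 <- 1 / (2 * sigma^2)
    norm <- inv2s2 / pi
    dens <- alpha * norm * exp(-d2t * inv2s2) + gamma * inv_area
    if (misbind && has_nt) {
      k <- exp(-d2nt * inv2s2)
      k[nt_na] <- 0
      dens <- dens + beta * norm * rowSums(k) * minv
    }
    if (any(dens <= 0)) return(1e10)
    -sum(log(dens))
  }
}

negloglik_plain_1d <- function(tm, model) {
  dt <- cos(tm$resp - tm$targ)
  has_nt <- ncol(tm$nt) > 0
  if (has_nt) {
    dnt <- cos(tm$resp - tm$nt)
    dim(dnt) <- dim(tm$nt)
    nt_na <- is.na(tm$nt)
    minv <- 1 / pmax(tm$m, 1)
  }
  misbind <- model$misbinding
  inv2pi <- 1 / (2 * pi)
  function(u) {
    if (misbind) {
      e1 <- exp(min(u[1], 30)); e2 <- exp(min(u[2], 30))
      s <- 1 + e1 + e2
      beta <- e1 / s; gamma <- e2 / s; alpha <- 1 / s
      kappa <- exp(u[3])
    } else {
      gamma <- stats::plogis(u[1]); beta <- 0; alpha <- 1 - gamma
      kappa <- exp(u[2])
    }
    if (kappa < 1e-4 || kappa > 1e4) return(1e10)
    norm <- inv2pi / besselI(kappa, 0, expon.scaled = TRUE)
    dens <- alpha * norm * exp(kappa * (dt - 1)) + gamma * inv2pi
    if (misbind && has_nt) {
      k <- exp(kappa * (dnt - 1))
      k[nt_na] <- 0
      dens <- dens + beta * norm * rowSums(k) * minv
    }
    if (any(dens <= 0)) return(1e10)
    -sum(log(dens))
  }
}

## coarse start grid over transformed parameters + method-of-moments start
start_points <- function(data, model, screen) {
  w_grid <- switch(
    as.character(sum(model$free_params %in% c("beta", "beta1", "beta2",
                                              "gamma"))),
    "1" = as.list(c(-2.2, 0, 2.2)),
    "2" = {
      g <- expand.grid(u1 = c(-2.2, 0, 2.2), u2 = c(-2.2, 0, 2.2))
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    },
    "3" = {
      g <- expand.grid(u1 = c(-2, 0, 2), u2 = c(-2, 0, 2), u3 = c(-2, 0, 2))
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    })
  spread_grid <- if (model$dim == 2)
    log(pmax(c(0.008, 0.04, 0.2) * max(screen$width, screen$height),
             SIGMA_MIN))
  else log(c(0.5, 4, 32))
  nbias <- sum(model$free_params %in% c("bias_x", "bias_y", "bias_prop"))
  starts <- list()
  for (w in w_grid) for (s in spread_grid)
    starts[[length(starts) + 1]] <- c(w, s, rep(0, nbias))
  mom <- moment_start(data, model, screen)
  if (!is.null(mom)) starts[[length(starts) + 1]] <- mom
  starts
}

moment_start <- function(data, model, screen) {
  if (model$response == "2afc") return(NULL)
  if (model$dim == 2) {
    tm <- trial_matrices(data)
    r2 <- (tm$resp[, 1] - tm$targ[, 1])^2 + (tm$resp[, 2] - tm$targ[, 2])^2
    ## lower-quartile of r^2 ~ 2 sigma^2 Exp(1) resists guess contamination
    s0 <- sqrt(stats::quantile(r2, 0.25) / (2 * 0.2877))
    s0 <- min(max(s0, SIGMA_MIN * 2), 0.3 * max(screen$width, screen$height))
    far <- r2 > (4 * s0)^2
    g0 <- min(max(mean(far), 0.05), 0.9)
    b0 <- 0.1
    p <- mixture_params(beta = if (model$misbinding) b0 else 0,
                        gamma = g0 * if (model$misbinding) 0.9 else 1,
                        sigma = s0,
                        beta1 = if (model$two_class) b0 / 2 else NULL,
                        beta2 = if (model$two_class) b0 / 2 else NULL)
    return(par_to_unconstrained(p, model))
  }
  tm <- trial_matrices_1d(data)
  dev <- wrap_angle(tm$resp - tm$targ)
  rbar <- sqrt(mean(cos(dev))^2 + mean(sin(dev))^2)
  k0 <- a1inv(rbar)
  k0 <- min(max(k0, 1e-3), 1e3)
  p <- mixture_params(beta = if (model$misbinding) 0.1 else 0, gamma = 0.2,
                      kappa = k0)
  par_to_unconstrained(p, model)
}

## Fisher's approximation to the inverse of I1/I0
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

## numerical covariance of the natural free parameters at the MLE
fit_vcov <- function(fit, data) {
  model <- fit$model
  screen <- fit$screen
  x0 <- par_to_natural(fit$params, model)
  negll_nat <- build_negloglik_natural(data, model, screen)
  H <- tryCatch(stats::optimHess(x0, negll_nat), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) dimnames(V) <- list(model$free_params, model$free_params)
  V
}
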