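#' MCMC posterior sampling
#'
#' Samples the posterior of the model's free parameters under flat priors
#' over their bounds (`beta, gamma >= 0` with `beta + gamma <= 1`; `sigma`
#' in `[0.01, max(width, height)]`; `kappa` in `[1e-4, 1e4]`), using
#' adaptive random-walk Metropolis in the natural parameter space. Three
#' chains are started overdispersed around the MLE; the proposal
#' covariance is adapted to the empirical covariance of each chain's
#' history during burn-in (scaled by `2.38^2 / d`). After burn-in the
#' chains are extended until the Gelman-Rubin potential scale reduction
#' factor of every parameter is below `rhat_threshold`, and at least
#' `n_retain` post-convergence draws are pooled across chains.
#'
#' @inheritParams fit_mle
#' @param n_retain Total retained draws across chains.
#' @param n_chains Number of chains.
#' @param burn_in Initial burn-in iterations per chain (with adaptation).
#' @param rhat_threshold Gelman-Rubin convergence threshold.
#' @param max_rounds The burn-in is re-run at doubled length up to this
#'   many times before a non-convergence error is raised.
#' @return An object of class `wm_posterior`: `draws` (matrix with one
#'   column per free parameter plus the derived `alpha`), `chain` labels,
#'   `rhat` diagnostics and the acceptance rate.
#' @export
fit_mcmc <- function(data, model = wm_model("misbind2d"),
                     screen = screen_geometry(), n_retain = 10000,
                     n_chains = 3, burn_in = 2000, rhat_threshold = 1.1,
                     max_rounds = 4) {
  screen <- if (model$dim == 2) as_screen(screen) else NULL
  mle <- fit_mle(data, model, if (is.null(screen)) screen_geometry()
                 else screen)
  x_mle <- par_to_natural(mle$params, model)
  d <- length(x_mle)
  negll <- build_negloglik_natural(data, model, screen)
  lower <- natural_lower(model)
  upper <- natural_upper(model, screen)

  per_chain <- ceiling(n_retain / n_chains)
  scale0 <- pmax(abs(x_mle) * 0.1, 0.02)

  for (round in seq_len(max_rounds)) {
    nb <- burn_in * 2^(round - 1)
    chains <- lapply(seq_len(n_chains), function(ch) {
      x0 <- overdispersed_start(x_mle, scale0, lower, upper, model, negll)
      run_metropolis(x0, negll, lower, upper, model, nb, per_chain, scale0)
    })
    draws <- lapply(chains, `[[`, "draws")
    rhat <- gelman_rubin(draws)
    if (all(rhat < rhat_threshold, na.rm = TRUE)) {
      all_draws <- do.call(rbind, draws)
      colnames(all_draws) <- model$free_params
      alpha <- compute_alpha_column(all_draws, model)
      all_draws <- cbind(all_draws, alpha = alpha)
      return(structure(list(
        draws = all_draws,
        chain = rep(seq_len(n_chains), each = per_chain),
        rhat = stats::setNames(rhat, model$free_params),
        accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")),
        model = model, mle = mle), class = "wm_posterior"))
    }
  }
  stop("MCMC did not converge: Gelman-Rubin diagnostics ",
       paste(sprintf("%s = %.3f", model$free_params, rhat), collapse = ", "),
       " after ", max_rounds, " rounds")
}

#' @export
print.wm_posterior <- function(x, ...) {
  cat(sprintf("<wm_posterior> %d draws x %d parameters, acceptance %.2f\n",
              nrow(x$draws), ncol(x$draws) - 1, x$accept_rate))
  cat("  R-hat:", paste(sprintf("%s %.3f", names(x$rhat), x$rhat),
                        collapse = ", "), "\n")
  invisible(x)
}

build_negloglik_natural <- function(data, model, screen) {
  tm <- if (model$response == "2afc") cd_matrices(data)
  else if (model$dim == 2) trial_matrices(data)
  else trial_matrices_1d(data)
  if (model$response == "2afc")
    tm$areas <- vapply(seq_len(tm$n), function(i)
      disc_rect_area(tm$targ[i, ], tm$d[i], screen), numeric(1))
  function(x) {
    par <- tryCatch(
      natural_to_par(stats::setNames(as.list(x), model$free_params), model),
      error = function(e) NULL)
    if (is.null(par)) return(Inf)
    if (model$response == "2afc") {
      ll <- loglik_2afc_tm(tm, par, model, screen)
      return(if (is.finite(ll)) -ll else Inf)
    }
    dens <- suppressWarnings(mixture_density(data, par, model, screen, tm))
    if (any(dens <= 0 | !is.finite(dens))) return(Inf)
    -sum(log(dens))
  }
}

natural_lower <- function(model) {
  vapply(model$free_params, function(nm) switch(nm,
    beta = , beta1 = , beta2 = , gamma = 0,
    sigma = SIGMA_MIN, kappa = 1e-4,
    bias_x = , bias_y = -Inf, bias_prop = -0.999), numeric(1))
}

natural_upper <- function(model, screen) {
  smax <- if (!is.null(screen)) max(screen$width, screen$height) else 1e4
  vapply(model$free_params, function(nm) switch(nm,
    beta = , beta1 = , beta2 = , gamma = 1,
    sigma = smax, kappa = 1e4,
    bias_x = , bias_y = Inf, bias_prop = 0.999), numeric(1))
}

in_support <- function(x, lower, upper, model) {
  if (any(x < lower | x > upper)) return(FALSE)
  w <- x[model$free_params %in% c("beta", "beta1", "beta2", "gamma")]
  sum(w) <= 1
}

overdispersed_start <- function(x_mle, scale0, lower, upper, model, negll) {
  for (i in 1:100) {
    x <- x_mle + stats::rnorm(length(x_mle), 0, 2 * scale0)
    if (in_support(x, lower, upper, model) && is.finite(negll(x))) return(x)
  }
  x_mle
}

run_metropolis <- function(x0, negll, lower, upper, model, n_burn, n_keep,
                           scale0) {
  d <- length(x0)
  x <- x0
  fx <- negll(x)
  prop_sd <- scale0
  prop_chol <- NULL
  history <- matrix(NA_real_, n_burn, d)
  accepted <- 0; total <- 0
  draws <- matrix(NA_real_, n_keep, d)
  n_total <- n_burn + n_keep
  for (i in seq_len(n_total)) {
    step <- if (is.null(prop_chol)) stats::rnorm(d, 0, prop_sd)
    else as.numeric(stats::rnorm(d) %*% prop_chol)
    cand <- x + step
    if (in_support(cand, lower, upper, model)) {
      fc <- negll(cand)
      if (is.finite(fc) && log(stats::runif(1)) < fx - fc) {
        x <- cand; fx <- fc
        if (i > n_burn) accepted <- accepted + 1
      }
    }
    if (i > n_burn) {
      total <- total + 1
      draws[i - n_burn, ] <- x
    } else {
      history[i, ] <- x
      ## adapt the proposal from the chain history, Haario-style
      if (i %% 200 == 0 && i >= 400) {
        S <- stats::cov(history[seq_len(i), , drop = FALSE])
        S <- S * (2.38^2 / d) + diag(1e-10, d)
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch)) prop_chol <- ch
      }
    }
  }
  list(draws = draws, accept_rate = accepted / max(total, 1))
}

## classic Gelman-Rubin potential scale reduction factor per parameter
gelman_rubin <- function(draw_list) {
  m <- length(draw_list)
  n <- nrow(draw_list[[1]])
  d <- ncol(draw_list[[1]])
  vapply(seq_len(d), function(j) {
    means <- vapply(draw_list, function(dd) mean(dd[, j]), numeric(1))
    vars <- vapply(draw_list, function(dd) stats::var(dd[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

compute_alpha_column <- function(draws, model) {
  w <- intersect(colnames(draws), c("beta", "beta1", "beta2", "gamma"))
  1 - rowSums(draws[, w, drop = FALSE])
}

#' Pairwise correlations among posterior draws
#'
#' Pearson correlations among the mixture parameters over posterior draws,
#' quantifying the trade-offs the model permits between misbinding,
#' guessing and imprecision (responses remote from all stimuli can be
#' explained as guesses or as very imprecise memory).
#'
#' @param posterior A [fit_mcmc()] result.
#' @return Correlation matrix over the free parameters.
#' @export
tradeoff_correlations <- function(posterior) {
  stopifnot(inherits(posterior, "wm_posterior"))
  if (nrow(posterior$draws) < 2)
    stop("need at least two posterior draws")
  stats::cor(posterior$draws[, posterior$model$free_params, drop = FALSE])
}
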