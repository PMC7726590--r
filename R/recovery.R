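#' Parameter-recovery experiments
#'
#' `run_recovery()` is the end-to-end harness: for every sweep cell and
#' iteration it simulates a dataset at the cell's true parameters, fits
#' the model by maximum likelihood, and records true and recovered
#' parameters together with recovery errors (recovered minus true). For
#' 1D models the cell's `sigma` is interpreted as a circular SD in
#' degrees: it is converted to a von Mises `kappa` for simulation, and the
#' fitted `kappa` is converted back to a circular SD before errors are
#' computed, so imprecision is compared on matching scales.
#'
#' Individual fit failures are recorded (`converged = FALSE`, `NA`
#' estimates), not fatal.
#'
#' @param cells Sweep cells from [sweep_grid()] (columns `gamma`, `beta`,
#'   `sigma`; `alpha` derived).
#' @param design A [task_design()] (2D models).
#' @param model A [wm_model()]; 1D models use `n_trials`/`n_items` from
#'   `design`.
#' @param iterations Simulated datasets per cell.
#' @param n_refine Optimiser starts refined per fit (see [fit_mle()]).
#' @param progress Print a progress line every 50 cells.
#' @return A tibble with one row per cell x iteration: true parameters
#'   (`*_true`), recovered parameters (`*_hat`), errors (`*_err`) and a
#'   `converged` flag.
#' @export
run_recovery <- function(cells = sweep_grid(), design = task_design(),
                         model = wm_model("misbind2d"), iterations = 10,
                         n_refine = 2, progress = FALSE) {
  n_cells <- nrow(cells)
  rows <- vector("list", n_cells * iterations)
  idx <- 0
  for (r in seq_len(n_cells)) {
    true_gamma <- cells$gamma[r]; true_beta <- cells$beta[r]
    true_sigma <- cells$sigma[r]
    for (it in seq_len(iterations)) {
      idx <- idx + 1
      rows[[idx]] <- recover_once(true_beta, true_gamma, true_sigma, it,
                                  design, model, n_refine)
    }
    if (progress && r %% 50 == 0)
      message("recovery: cell ", r, " / ", n_cells)
  }
  tibble::as_tibble(do.call(rbind, rows))
}

recover_once <- function(true_beta, true_gamma, true_sigma, iteration,
                         design, model, n_refine) {
  if (model$dim == 2) {
    p <- mixture_params(beta = true_beta, gamma = true_gamma,
                        sigma = true_sigma)
    data <- simulate_responses(p, design)
    fit <- tryCatch(fit_mle(data, model, design$screen,
                            n_refine = n_refine),
                    error = function(e) NULL)
    hat <- if (is.null(fit)) list(beta = NA_real_, gamma = NA_real_,
                                  sigma = NA_real_)
    else fit$params
  } else {
    kappa <- sd_to_kappa(true_sigma * pi / 180)
    p <- mixture_params(beta = true_beta, gamma = true_gamma, kappa = kappa)
    data <- simulate_responses_1d(p, n_trials = design$n_trials,
                                  n_items = design$n_items)
    fit <- tryCatch(fit_mle(data, model, n_refine = n_refine),
                    error = function(e) NULL)
    hat <- if (is.null(fit)) list(beta = NA_real_, gamma = NA_real_)
    else fit$params
    hat$sigma <- if (is.null(fit)) NA_real_
    else kappa_to_sd(fit$params$kappa) * 180 / pi
  }
  beta_hat <- if (model$misbinding) hat$beta else 0
  data.frame(
    iteration = iteration,
    beta_true = true_beta, gamma_true = true_gamma,
    sigma_true = true_sigma, alpha_true = 1 - true_beta - true_gamma,
    beta_hat = beta_hat, gamma_hat = hat$gamma, sigma_hat = hat$sigma,
    alpha_hat = 1 - beta_hat - hat$gamma,
    beta_err = beta_hat - true_beta, gamma_err = hat$gamma - true_gamma,
    sigma_err = hat$sigma - true_sigma,
    alpha_err = (1 - beta_hat - hat$gamma) - (1 - true_beta - true_gamma),
    converged = !is.null(fit) && fit$convergence)
}

#' Spearman correlations between true and recovered parameters
#'
#' Pools all recovery records and computes, per parameter (`sigma`,
#' `alpha`, `beta`, `gamma`), the Spearman rank correlation between true
#' and recovered values — the headline summary of recovery quality.
#'
#' @param records A [run_recovery()] result (>= 10 records).
#' @return Named numeric vector of Spearman rho values.
#' @export
recovery_correlations <- function(records) {
  records <- records[stats::complete.cases(
    records[, c("sigma_hat", "gamma_hat", "beta_hat")]), ]
  if (nrow(records) < 10) stop("need at least 10 complete recovery records")
  out <- vapply(c("sigma", "alpha", "beta", "gamma"), function(p) {
    x <- records[[paste0(p, "_true")]]
    y <- records[[paste0(p, "_hat")]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  out
}

#' Compare recovery accuracy across design factors
#'
#' Runs the recovery harness at each level of a design factor (number of
#' trials, number of nontargets, or constrained versus unconstrained
#' stimulus placement) and summarises mean absolute recovery error per
#' parameter and level, with a per-parameter linear trend test of
#' `|error|` on the level.
#'
#' @param factor `"trials"`, `"nontargets"` or `"constraints"`.
#' @param levels Factor levels: trial counts, nontarget counts, or
#'   `c(FALSE, TRUE)` for constraints.
#' @param cells Sweep cells to run at each level.
#' @param model A [wm_model()].
#' @param iterations Iterations per cell and level.
#' @param screen A [screen_geometry()].
#' @return A list: `summary` (tibble of level x parameter mean absolute
#'   errors) and `trend` (per-parameter slope p-values; `NULL` for the
#'   two-level constraints factor).
#' @export
compare_designs <- function(factor = c("trials", "nontargets",
                                       "constraints"),
                            levels, cells, model = wm_model("misbind2d"),
                            iterations = 5, screen = screen_geometry()) {
  factor <- match.arg(factor)
  stopifnot(length(levels) >= 2)
  runs <- lapply(levels, function(lev) {
    design <- switch(factor,
      trials = task_design(n_trials = lev, screen = screen),
      nontargets = task_design(n_items = lev + 1, screen = screen),
      constraints = if (lev) constrained_design(screen = screen)
      else task_design(screen = screen))
    rec <- run_recovery(cells, design, model, iterations = iterations)
    rec$level <- lev
    rec
  })
  all <- tibble::as_tibble(do.call(rbind, runs))
  params <- c("alpha", "beta", "gamma", "sigma")
  summary <- do.call(rbind, lapply(params, function(p) {
    agg <- stats::aggregate(abs(all[[paste0(p, "_err")]]),
                            by = list(level = all$level),
                            FUN = mean, na.rm = TRUE)
    data.frame(param = p, level = agg$level, mean_abs_error = agg$x)
  }))
  trend <- NULL
  if (is.numeric(levels) && length(unique(levels)) > 2) {
    trend <- vapply(params, function(p) {
      y <- abs(all[[paste0(p, "_err")]])
      ok <- is.finite(y)
      fit <- stats::lm(y[ok] ~ all$level[ok])
      stats::coef(summary(fit))[2, c(1, 4)]
    }, numeric(2))
    rownames(trend) <- c("slope", "p_value")
  }
  list(summary = tibble::as_tibble(summary), trend = trend, records = all)
}

#' Paired comparison of bias-corrected and uncorrected fits
#'
#' Simulates data with a known response bias at each bias magnitude,
#' fits both the plain model and the bias-corrected model to the same
#' datasets, and reports mean absolute recovery error for each.
#'
#' @param kind `"constant"`, `"edge"`, `"radial"` or
#'   `"radial_nontarget"` (per-trial nontarget pull; simulated with one
#'   nontarget and no misbinding).
#' @param bias_values Bias magnitudes: translation lengths for
#'   `"constant"` (applied along x), proportions otherwise.
#' @param cells Sweep cells (generating mixture parameters).
#' @param iterations Datasets per cell and bias value.
#' @param screen A [screen_geometry()].
#' @return A tibble with per-parameter mean absolute errors for the
#'   uncorrected and corrected fits at each bias value.
#' @export
compare_bias_correction <- function(kind = c("constant", "edge", "radial",
                                             "radial_nontarget"),
                                    bias_values = seq(20, 200, by = 36),
                                    cells = NULL, iterations = 2,
                                    screen = screen_geometry()) {
  kind <- match.arg(kind)
  screen <- as_screen(screen)
  if (is.null(cells))
    cells <- data.frame(beta = c(0.1, 0.3), gamma = c(0.1, 0.3),
                        sigma = c(30, 50))
  pull <- kind == "radial_nontarget"
  base_type <- if (pull) "standard2d" else "misbind2d"
  gen_model <- wm_model(base_type,
                        bias = switch(kind, constant = "constant",
                                      edge = "edge", radial = "radial",
                                      radial_nontarget = "radial"),
                        bias_center = if (pull) "nontarget"
                        else "screen_center")
  fit_plain <- wm_model(base_type)
  fit_corr <- gen_model
  design <- task_design(n_items = if (pull) 2 else 3, screen = screen)

  rows <- list()
  for (bv in bias_values) {
    bias <- switch(kind, constant = c(bias_x = bv, bias_y = 0),
                   c(bias_prop = bv))
    for (r in seq_len(nrow(cells))) for (it in seq_len(iterations)) {
      p <- mixture_params(beta = if (pull) 0 else cells$beta[r],
                          gamma = cells$gamma[r], sigma = cells$sigma[r],
                          bias = bias)
      data <- simulate_responses(p, design, gen_model)
      for (corrected in c(FALSE, TRUE)) {
        model <- if (corrected) fit_corr else fit_plain
        fit <- tryCatch(fit_mle(data, model, screen), error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1]] <- data.frame(
          bias_value = bv, corrected = corrected,
          beta_true = p$beta, gamma_true = p$gamma, sigma_true = p$sigma,
          beta_hat = fit$params$beta, gamma_hat = fit$params$gamma,
          sigma_hat = fit$params$sigma, bic = fit$bic,
          abs_err = mean(c(abs(fit$params$gamma - p$gamma),
                           abs(fit$params$beta - p$beta),
                           abs(fit$params$sigma - p$sigma) /
                             max(p$sigma, 1))))
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
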