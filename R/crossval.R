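#' Cross-validated comparison of guess distributions
#'
#' Repeatedly splits a participant's trials into a random 90% training and
#' 10% validation set, fits each candidate model to the training set, and
#' evaluates the held-out trials under the fitted parameters. For models
#' with a KDE guess distribution the response-sampling density is rebuilt
#' from the training responses only, so held-out likelihoods are not
#' inflated by overfitting. The comparison statistic is the arithmetic
#' mean of per-trial held-out likelihoods (densities), averaged over
#' repetitions; set `statistic = "log_likelihood"` for the mean held-out
#' log-likelihood instead.
#'
#' @param data Trial data frame.
#' @param models Named list of [wm_model()]s to compare. Models whose
#'   `guess` is `"kde"` are refitted with a training-set KDE each split.
#' @param screen A [screen_geometry()].
#' @param reps Number of random splits.
#' @param holdout Held-out fraction.
#' @param statistic `"likelihood"` or `"log_likelihood"`.
#' @return A tibble with one row per model: the mean held-out statistic
#'   and its SD over repetitions.
#' @export
crossval_response_sampling <- function(data,
                                       models = list(
                                         uniform = wm_model("misbind2d"),
                                         kde = with_kde_guess(
                                           wm_model("misbind2d"))),
                                       screen = screen_geometry(),
                                       reps = 100, holdout = 0.1,
                                       statistic = c("likelihood",
                                                     "log_likelihood")) {
  statistic <- match.arg(statistic)
  screen <- as_screen(screen)
  n <- nrow(data)
  if (n < 20) stop("cross-validation needs at least 20 trials")
  n_test <- max(1, round(holdout * n))
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  results <- matrix(NA_real_, reps, length(models),
                    dimnames = list(NULL, names(models)))
  for (r in seq_len(reps)) {
    test_idx <- sample.int(n, n_test)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    for (mi in seq_along(models)) {
      model <- models[[mi]]
      if (identical(model$guess, "kde") || isTRUE(model$want_kde)) {
        kde <- build_response_kde(cbind(train$resp_x, train$resp_y),
                                  screen = screen)
        model <- kde_guess_model(model, kde)
      }
      fit <- fit_mle(train, model, screen)
      dens <- suppressWarnings(mixture_density(test, fit$params, model,
                                               screen))
      results[r, mi] <- if (statistic == "likelihood") mean(dens)
      else mean(log(pmax(dens, 1e-300)))
    }
  }
  tibble::tibble(model = names(models),
                 mean_heldout = colMeans(results),
                 sd_heldout = apply(results, 2, stats::sd),
                 reps = reps, statistic = statistic)
}

#' Request a training-set KDE guess inside cross-validation
#'
#' Marks a model so [crossval_response_sampling()] rebuilds its guess KDE
#' from each training split (the model itself keeps a uniform guess until
#' then).
#'
#' @param model A 2D [wm_model()].
#' @export
with_kde_guess <- function(model) {
  stopifnot(inherits(model, "wm_model"))
  model$want_kde <- TRUE
  model
}
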