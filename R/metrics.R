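#' Distance-based behavioural metrics
#'
#' `target_distance()` returns the per-trial Euclidean distance from the
#' response to the target; its mean is the most basic performance summary
#' and mixes imprecision, guessing and misbinding. `nearest_neighbor_distance()`
#' returns the distance from the response to the nearest displayed item
#' (target or nontarget; ties go to the target), which removes the
#' misbinding contribution. The difference of their means indexes
#' misbinding.
#'
#' @param data Trial data frame (see [trial-data]).
#' @return Numeric vector of per-trial distances.
#' @export
target_distance <- function(data) {
  tm <- trial_matrices(data)
  sqrt((tm$resp[, 1] - tm$targ[, 1])^2 + (tm$resp[, 2] - tm$targ[, 2])^2)
}

#' @rdname target_distance
#' @export
nearest_neighbor_distance <- function(data) {
  tm <- trial_matrices(data)
  d <- target_distance(data)
  if (ncol(tm$ntx)) {
    d2 <- (tm$ntx - tm$resp[, 1])^2 + (tm$nty - tm$resp[, 2])^2
    d2[is.na(d2)] <- Inf
    dnt <- sqrt(do.call(pmin, c(as.data.frame(d2), list(Inf))))
    d <- pmin(d, dnt)  # pmin keeps the target on ties
  }
  d
}

## per-trial distance to the nearest nontarget (Inf when none)
nearest_nontarget_distance <- function(tm) {
  if (ncol(tm$ntx) == 0) return(rep(Inf, tm$n))
  d2 <- (tm$ntx - tm$resp[, 1])^2 + (tm$nty - tm$resp[, 2])^2
  d2[is.na(d2)] <- Inf
  sqrt(do.call(pmin, c(as.data.frame(d2), list(Inf))))
}

#' Swap-error proportion
#'
#' The proportion of trials whose response falls within `threshold` of a
#' nontarget. The default threshold is 1.5 visual degrees (~44 px at a
#' 40 cm viewing distance and 42 px/cm). Because imprecise target
#' responses can land near a nontarget by chance, the chance-corrected
#' mode subtracts, per trial, the fraction of candidate locations at the
#' response's distance from the target that would themselves count as
#' swaps: `n_circle` evenly spaced points on the circle of radius equal to
#' the trial's target distance, centred on the target, with off-screen
#' points dropped before the fraction is computed.
#'
#' `swap_errors_mean_threshold()` instead uses the dataset's mean target
#' distance as the threshold, scaling the criterion by the participant's
#' average accuracy.
#'
#' @param data Trial data frame.
#' @param screen A [screen_geometry()].
#' @param threshold Swap distance threshold (length units).
#' @param chance_corrected Apply the chance correction (default `TRUE`).
#' @param n_circle Number of candidate points for the correction.
#' @return The (possibly corrected) swap proportion; `NA` with a warning
#'   when the dataset has no nontargets.
#' @export
swap_errors <- function(data, screen = screen_geometry(),
                        threshold = degrees_to_px(1.5),
                        chance_corrected = TRUE, n_circle = 360) {
  stopifnot(threshold > 0)
  screen <- as_screen(screen)
  tm <- trial_matrices(data)
  if (ncol(tm$ntx) == 0 || all(tm$m == 0)) {
    warning("no nontargets in dataset; swap errors are undefined")
    return(NA_real_)
  }
  dnt <- nearest_nontarget_distance(tm)
  swaps <- as.numeric(dnt < threshold)
  if (!chance_corrected) return(mean(swaps))
  r <- target_distance(data)
  ang <- seq(0, 2 * pi, length.out = n_circle + 1)[-(n_circle + 1)]
  ## n x n_circle candidate locations on each trial's target-distance circle
  cx <- tm$targ[, 1] + outer(r, cos(ang))
  cy <- tm$targ[, 2] + outer(r, sin(ang))
  keep <- cx >= 0 & cx <= screen$width & cy >= 0 & cy <= screen$height
  near <- matrix(FALSE, tm$n, n_circle)
  for (j in seq_len(ncol(tm$ntx))) {
    dj <- (cx - tm$ntx[, j])^2 + (cy - tm$nty[, j])^2 < threshold^2
    dj[is.na(dj)] <- FALSE
    near <- near | dj
  }
  n_keep <- rowSums(keep)
  correction <- ifelse(n_keep > 0, rowSums(near & keep) / n_keep, 0)
  mean(swaps - correction)
}

#' @rdname swap_errors
#' @export
swap_errors_mean_threshold <- function(data, screen = screen_geometry(),
                                       chance_corrected = TRUE,
                                       n_circle = 360) {
  thr <- mean(target_distance(data))
  if (thr <= 0) return(0)
  swap_errors(data, screen, threshold = thr,
              chance_corrected = chance_corrected, n_circle = n_circle)
}

#' Split-half reliability of a measure
#'
#' Per iteration, each participant's trials are randomly split in half,
#' the measure is computed on each half, and the two halves are
#' Spearman-correlated across participants; the reliability coefficient
#' is the mean correlation over iterations.
#'
#' @param datasets List of per-participant trial data frames (>= 2
#'   participants with >= 4 trials each).
#' @param measure A `function(data)` returning one number per dataset.
#' @param iterations Number of random splits.
#' @return Mean Spearman correlation; `NA` with a warning if the measure
#'   is constant across participants.
#' @export
split_half_reliability <- function(datasets, measure, iterations = 100) {
  stopifnot(length(datasets) >= 2,
            all(vapply(datasets, nrow, integer(1)) >= 4))
  rhos <- vapply(seq_len(iterations), function(it) {
    halves <- vapply(datasets, function(d) {
      n <- nrow(d)
      idx <- sample.int(n, floor(n / 2))
      c(measure(d[idx, , drop = FALSE]), measure(d[-idx, , drop = FALSE]))
    }, numeric(2))
    suppressWarnings(stats::cor(halves[1, ], halves[2, ],
                                method = "spearman"))
  }, numeric(1))
  if (all(is.na(rhos))) {
    warning("measure is constant across participants; reliability undefined")
    return(NA_real_)
  }
  mean(rhos, na.rm = TRUE)
}
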