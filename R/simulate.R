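#' Task design for simulated spatial working-memory experiments
#'
#' Describes the simulated task: number of trials, number of items (one
#' target plus `n_items - 1` nontargets), the screen, and optional
#' stimulus-placement constraints (minimum pairwise item distance, minimum
#' distance from the screen centre, minimum distance from the screen
#' edges). The default is the canonical 3-item task on a 1366 x 768 screen
#' with 100 trials and unconstrained (uniform) placement.
#'
#' @param n_trials Number of trials.
#' @param n_items Items per trial (1 target + m nontargets).
#' @param screen A [screen_geometry()].
#' @param min_item_distance Minimum pairwise distance between items.
#' @param min_edge_distance Minimum distance of any item from the edges.
#' @param min_center_distance Minimum distance of any item from the centre.
#' @param nontarget_classes Optional class labels (length `n_items - 1`)
#'   attached to the nontargets, for the two-class misbinding model.
#' @param max_attempts Rejection-sampling cap per trial before erroring.
#' @return An object of class `task_design`.
#' @export
task_design <- function(n_trials = 100, n_items = 3,
                        screen = screen_geometry(),
                        min_item_distance = 0, min_edge_distance = 0,
                        min_center_distance = 0, nontarget_classes = NULL,
                        max_attempts = 1e4) {
  screen <- as_screen(screen)
  stopifnot(n_trials >= 1, n_items >= 1)
  if (2 * min_edge_distance >= min(screen$width, screen$height))
    stop("edge margin leaves no feasible placement area")
  if (!is.null(nontarget_classes) &&
      length(nontarget_classes) != n_items - 1)
    stop("`nontarget_classes` must have one label per nontarget")
  structure(list(n_trials = n_trials, n_items = n_items, screen = screen,
                 min_item_distance = min_item_distance,
                 min_edge_distance = min_edge_distance,
                 min_center_distance = min_center_distance,
                 nontarget_classes = nontarget_classes,
                 max_attempts = max_attempts),
            class = "task_design")
}

#' @rdname task_design
#' @param ... Overrides passed on to [task_design()].
#' @details `constrained_design()` applies the conventional spacing rules
#'   for spatial WM displays: items at least 88 px (3 visual degrees at
#'   40 cm and 42 px/cm) from each other and from the screen centre, and at
#'   least 29 px (1 degree) from the screen edges.
#' @export
constrained_design <- function(...) {
  task_design(min_item_distance = 88, min_edge_distance = 29,
              min_center_distance = 88, ...)
}

#' Generate stimulus locations
#'
#' Places `n_items` items per trial uniformly at random on the screen,
#' subject to the design's spacing constraints, via batched rejection
#' sampling. Item 1 is the target.
#'
#' @param design A [task_design()].
#' @return A tibble with `targ_x`, `targ_y` and `nt{i}_x`, `nt{i}_y`
#'   (plus `nt{i}_class` if the design has nontarget classes).
#' @export
generate_stimuli <- function(design) {
  stopifnot(inherits(design, "task_design"))
  scr <- design$screen
  k <- design$n_items
  n <- design$n_trials
  med <- design$min_edge_distance
  lo <- c(med, med)
  hi <- c(scr$width - med, scr$height - med)
  cx <- scr$width / 2; cy <- scr$height / 2

  kept <- matrix(NA_real_, 0, 2 * k)
  attempts <- 0
  fail_pair <- fail_center <- 0
  while (nrow(kept) < n) {
    b <- max(2 * (n - nrow(kept)), 64)
    attempts <- attempts + b
    if (attempts > design$max_attempts * n)
      stop("stimulus placement failed after ", attempts, " attempts; ",
           "most violated constraint: ",
           if (fail_pair >= fail_center) "min_item_distance"
           else "min_center_distance")
    xs <- matrix(stats::runif(b * k, lo[1], hi[1]), b, k)
    ys <- matrix(stats::runif(b * k, lo[2], hi[2]), b, k)
    ok <- rep(TRUE, b)
    if (design$min_item_distance > 0 && k > 1) {
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        d2 <- (xs[, i] - xs[, j])^2 + (ys[, i] - ys[, j])^2
        bad <- d2 < design$min_item_distance^2
        fail_pair <- fail_pair + sum(bad & ok)
        ok <- ok & !bad
      }
    }
    if (design$min_center_distance > 0) {
      for (i in seq_len(k)) {
        bad <- (xs[, i] - cx)^2 + (ys[, i] - cy)^2 <
          design$min_center_distance^2
        fail_center <- fail_center + sum(bad & ok)
        ok <- ok & !bad
      }
    }
    if (any(ok))
      kept <- rbind(kept, cbind(xs[ok, , drop = FALSE],
                                ys[ok, , drop = FALSE]))
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  out <- tibble::tibble(targ_x = kept[, 1], targ_y = kept[, k + 1])
  for (i in seq_len(k - 1)) {
    out[[paste0("nt", i, "_x")]] <- kept[, 1 + i]
    out[[paste0("nt", i, "_y")]] <- kept[, k + 1 + i]
    if (!is.null(design$nontarget_classes))
      out[[paste0("nt", i, "_class")]] <- design$nontarget_classes[i]
  }
  out
}

## isotropic Gaussian draws around per-row centers, resampled until
## on-screen (the generative model's screen rule)
rnorm2_on_screen <- function(centers, sigma, screen) {
  n <- nrow(centers)
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- centers[todo, , drop = FALSE] +
      matrix(stats::rnorm(2 * length(todo), 0, sigma), ncol = 2)
    ok <- on_screen(cand, screen)
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out
}

#' Simulate continuous-report responses
#'
#' Draws one response per trial from the generative mixture: with
#' probability `alpha` a Gaussian draw (SD `sigma`) around the target, with
#' probability `beta` around a uniformly chosen nontarget, and with
#' probability `gamma` a guess, uniform over the screen (or drawn from the
#' model's KDE guess distribution, or from `guess_sampler`). Gaussian draws
#' falling off-screen are replaced by fresh draws from the same
#' distribution. If the model carries a bias and `params$bias` is set, the
#' bias transform is applied to the responses afterwards and the result is
#' clipped to the screen.
#'
#' @param params A [mixture_params()] (2D: needs `sigma`).
#' @param design A [task_design()]; ignored when `stimuli` is given.
#' @param model A [wm_model()] controlling guess distribution and bias.
#' @param stimuli Optional precomputed stimulus tibble from
#'   [generate_stimuli()].
#' @param guess_sampler Optional `function(n)` returning an `n x 2` matrix
#'   of guess locations (overrides the model's guess distribution).
#' @return A tibble of trials (see [trial-data]) with a `resp_type` column
#'   recording the generative component of each response.
#' @export
simulate_responses <- function(params, design = task_design(),
                               model = wm_model("misbind2d"),
                               stimuli = NULL, guess_sampler = NULL) {
  params <- as_mixture_params(params)
  if (is.null(params$sigma)) stop("2D simulation requires `sigma`")
  scr <- design$screen
  if (is.null(stimuli)) stimuli <- generate_stimuli(design)
  n <- nrow(stimuli)
  tm <- trial_matrices(cbind(resp_x = 0, resp_y = 0, stimuli))

  if (!is.null(params$beta1)) {
    type <- draw_two_class_types(params, tm)
  } else {
    probs <- c(target = params$alpha, nontarget = params$beta,
               guess = params$gamma)
    type <- sample(names(probs), n, replace = TRUE, prob = probs)
    type[type == "nontarget" & tm$m == 0] <- "target"
  }

  resp <- matrix(NA_real_, n, 2)
  is_t <- type == "target"
  is_nt <- startsWith(type, "nontarget")
  is_g <- type == "guess"
  if (any(is_t))
    resp[is_t, ] <- rnorm2_on_screen(tm$targ[is_t, , drop = FALSE],
                                     params$sigma, scr)
  if (any(is_nt)) {
    idx <- which(is_nt)
    centers <- t(vapply(idx, function(i) {
      cols <- which(!is.na(tm$ntx[i, ]))
      if (type[i] == "nontarget1") cols <- cols[tm$class[i, cols] == 1]
      if (type[i] == "nontarget2") cols <- cols[tm$class[i, cols] == 2]
      j <- if (length(cols) == 1) cols else sample(cols, 1)
      c(tm$ntx[i, j], tm$nty[i, j])
    }, numeric(2)))
    resp[idx, ] <- rnorm2_on_screen(centers, params$sigma, scr)
  }
  if (any(is_g)) {
    ng <- sum(is_g)
    resp[is_g, ] <- if (!is.null(guess_sampler)) guess_sampler(ng)
    else if (model$guess == "kde") kde_sample(model$kde, ng)
    else cbind(stats::runif(ng, 0, scr$width),
               stats::runif(ng, 0, scr$height))
  }

  if (model$bias != "none" && !is.null(params$bias)) {
    centers <- resolve_bias_center(model, tm, scr)
    resp <- apply_bias_to_responses(resp, model, params$bias, scr, centers)
  }

  out <- tibble::tibble(resp_x = resp[, 1], resp_y = resp[, 2],
                        resp_type = type)
  tibble::as_tibble(cbind(out, stimuli))
}

draw_two_class_types <- function(params, tm) {
  n <- tm$n
  type <- character(n)
  has1 <- rowSums(!is.na(tm$class) & tm$class == 1) > 0
  has2 <- rowSums(!is.na(tm$class) & tm$class == 2) > 0
  for (i in seq_len(n)) {
    p <- c(target = params$alpha,
           nontarget1 = if (has1[i]) params$beta1 else 0,
           nontarget2 = if (has2[i]) params$beta2 else 0,
           guess = params$gamma)
    type[i] <- sample(names(p), 1, prob = p)  # renormalised over present classes
  }
  type
}

#' Simulate 1D (circular) continuous-report responses
#'
#' The circular analogue of [simulate_responses()]: target and nontarget
#' orientations are uniform on the circle, target/misbinding responses are
#' von Mises draws (concentration `kappa`) around the chosen item, and
#' guesses are uniform over `[-pi, pi)`. No resampling rule is needed
#' because the circle has no edges.
#'
#' @param params A [mixture_params()] with `kappa`.
#' @param n_trials,n_items Task size (1 target + `n_items - 1` nontargets).
#' @return A tibble with `resp`, `targ`, `nt{i}` (radians) and `resp_type`.
#' @export
simulate_responses_1d <- function(params, n_trials = 100, n_items = 3) {
  params <- as_mixture_params(params)
  if (is.null(params$kappa)) stop("1D simulation requires `kappa`")
  m <- n_items - 1
  targ <- stats::runif(n_trials, -pi, pi)
  nt <- if (m > 0) matrix(stats::runif(n_trials * m, -pi, pi), n_trials, m)
  else NULL
  probs <- c(target = params$alpha, nontarget = params$beta,
             guess = params$gamma)
  type <- sample(names(probs), n_trials, replace = TRUE, prob = probs)
  if (m == 0) type[type == "nontarget"] <- "target"
  center <- targ
  if (any(type == "nontarget")) {
    idx <- which(type == "nontarget")
    j <- sample.int(m, length(idx), replace = TRUE)
    center[idx] <- nt[cbind(idx, j)]
  }
  resp <- wrap_angle(center + rvonmises(n_trials, params$kappa))
  resp[type == "guess"] <- stats::runif(sum(type == "guess"), -pi, pi)
  out <- tibble::tibble(resp = resp, targ = targ, resp_type = type)
  if (m > 0) for (i in seq_len(m)) out[[paste0("nt", i)]] <- nt[, i]
  out
}

## von Mises sampler (Best & Fisher 1979 rejection scheme), mean 0
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    todo <- n - length(out)
    u1 <- stats::runif(todo); u2 <- stats::runif(todo); u3 <- stats::runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    out <- c(out, theta)
  }
  out[seq_len(n)]
}

#' Parameter sweep grids and sweep simulation
#'
#' `sweep_grid()` builds the canonical recovery sweep: `n_values` evenly
#' spaced values of the guessing and misbinding proportions over
#' `[0.01, 0.98]` and of the imprecision over `[0.1, 100]`, crossed, with
#' cells where `gamma + beta > 1` excluded.
#'
#' `simulate_sweep()` simulates `iterations` datasets for every cell.
#'
#' @param n_values Grid points per parameter.
#' @param gamma_range,beta_range,sigma_range Parameter ranges.
#' @return `sweep_grid()`: a tibble with columns `gamma`, `beta`, `sigma`
#'   and derived `alpha`; `simulate_sweep()`: a list of
#'   `list(params, data)` entries, one per cell x iteration.
#' @export
sweep_grid <- function(n_values = 11, gamma_range = c(0.01, 0.98),
                       beta_range = c(0.01, 0.98),
                       sigma_range = c(0.1, 100)) {
  g <- seq(gamma_range[1], gamma_range[2], length.out = n_values)
  b <- seq(beta_range[1], beta_range[2], length.out = n_values)
  s <- seq(sigma_range[1], sigma_range[2], length.out = n_values)
  cells <- expand.grid(gamma = g, beta = b, sigma = s,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[cells$gamma + cells$beta <= 1, , drop = FALSE]
  cells$alpha <- 1 - cells$gamma - cells$beta
  tibble::as_tibble(cells)
}

#' @rdname sweep_grid
#' @param cells Sweep cells from [sweep_grid()].
#' @param design A [task_design()].
#' @param iterations Datasets per cell.
#' @export
simulate_sweep <- function(cells = sweep_grid(), design = task_design(),
                           iterations = 1) {
  out <- vector("list", nrow(cells) * iterations)
  idx <- 1
  for (r in seq_len(nrow(cells))) {
    p <- mixture_params(beta = cells$beta[r], gamma = cells$gamma[r],
                        sigma = cells$sigma[r])
    for (it in seq_len(iterations)) {
      out[[idx]] <- list(params = p, iteration = it,
                         data = simulate_responses(p, design))
      idx <- idx + 1
    }
  }
  out
}

#' Simulate the ignore/update two-class fixture task
#'
#' A synthetic version of a task with two kinds of nonprobed items: half
#' the trials carry three nontargets (one of class 1, the nonprobed test
#' item, and two of class 2, distractors) and half carry a single class-1
#' nontarget. Misbinding is drawn class-wise from `beta1`/`beta2`; on
#' trials lacking a class the remaining weights are renormalised.
#'
#' @param params A [mixture_params()] with `beta1`, `beta2`.
#' @param n_trials Total trials (split evenly between trial types).
#' @param screen A [screen_geometry()].
#' @export
simulate_ignore_update <- function(params, n_trials = 120,
                                   screen = screen_geometry()) {
  n1 <- floor(n_trials / 2)
  d3 <- task_design(n_trials = n1, n_items = 4, screen = screen,
                    nontarget_classes = c(1, 2, 2))
  d1 <- task_design(n_trials = n_trials - n1, n_items = 2, screen = screen,
                    nontarget_classes = 1)
  a <- simulate_responses(params, d3)
  b <- simulate_responses(params, d1)
  a$condition <- "ignore_update"
  b$condition <- "maintain"
  merge_trial_sets(a, b)
}

## row-bind trial tibbles with differing nontarget counts (pad with NA)
merge_trial_sets <- function(...) {
  sets <- list(...)
  cols <- unique(unlist(lapply(sets, names)))
  sets <- lapply(sets, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  })
  tibble::as_tibble(do.call(rbind, sets))
}
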