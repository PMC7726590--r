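#' Change-detection (2AFC) likelihoods
#'
#' In a change-detection trial a probe is shown displaced from the target
#' by a distance `d > 0` and the participant judges whether the location
#' changed. The model predicts the probability of (correctly) rejecting
#' the probe as changed as the probability that the continuous-report
#' mixture would generate a response closer to the target than the probe
#' is: the integral of the mixture density over the on-screen disc of
#' radius `d` around the target. Anyone who accepts a probe at distance
#' `d` would therefore also have accepted smaller displacements, which is
#' exactly the integral formulation; no extra lapse parameter exists.
#'
#' Data columns: `targ_x`, `targ_y`, `probe_x`, `probe_y`, optional
#' `nt{i}_x`/`nt{i}_y`, and (for the likelihood) `response`, coded 1 when
#' the participant rejected the probe as changed and 0 when they accepted
#' it as unchanged.
#'
#' @param data Change-detection data frame.
#' @param params A [mixture_params()] with `sigma`.
#' @param screen A [screen_geometry()].
#' @param model A 2AFC [wm_model()] (`"standard2afc"` or `"misbind2afc"`).
#' @param method `"analytic"` evaluates the Gaussian components by the
#'   noncentral chi-square disc integral (ignoring screen truncation of the
#'   Gaussians, consistent with the untruncated fitting density) and the
#'   uniform component by the exact disc-rectangle overlap; `"quadrature"`
#'   integrates the full density on a polar grid clipped to the screen.
#' @return `p_reject()`: per-trial rejection probabilities, non-decreasing
#'   in the probe distance; `loglik_2afc()`: the Bernoulli log-likelihood.
#' @export
p_reject <- function(data, params, screen = screen_geometry(),
                     model = wm_model("standard2afc"),
                     method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  tm <- cd_matrices(data)
  params <- as_mixture_params(params)
  screen <- as_screen(screen)
  if (method == "analytic") p_reject_analytic(tm, params, screen)
  else p_reject_quadrature(tm, params, model, screen)
}

cd_matrices <- function(data) {
  need <- c("targ_x", "targ_y", "probe_x", "probe_y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("change-detection data missing columns: ",
         paste(miss, collapse = ", "))
  n <- nrow(data)
  targ <- cbind(data$targ_x, data$targ_y)
  probe <- cbind(data$probe_x, data$probe_y)
  d <- sqrt(rowSums((probe - targ)^2))
  if (any(d <= 0))
    stop("probe displacement must be positive on every trial (trial(s) ",
         paste(utils::head(which(d <= 0), 5), collapse = ", "), ")")
  nt_idx <- sort(as.integer(sub("^nt([0-9]+)_x$", "\\1",
                                grep("^nt[0-9]+_x$", names(data),
                                     value = TRUE))))
  if (length(nt_idx)) {
    ntx <- matrix(sapply(nt_idx, function(i) data[[paste0("nt", i, "_x")]]),
                  nrow = n)
    nty <- matrix(sapply(nt_idx, function(i) data[[paste0("nt", i, "_y")]]),
                  nrow = n)
  } else ntx <- nty <- matrix(numeric(0), nrow = n, ncol = 0)
  m <- if (ncol(ntx)) rowSums(!is.na(ntx)) else rep(0L, n)
  response <- if ("response" %in% names(data)) as.numeric(data$response)
  else rep(NA_real_, n)
  list(targ = targ, probe = probe, d = d, ntx = ntx, nty = nty,
       m = as.numeric(m), response = response, n = n)
}

p_reject_analytic <- function(tm, params, screen) {
  s2 <- params$sigma^2
  p <- params$alpha * stats::pchisq(tm$d^2 / s2, df = 2)
  if (params$beta > 0 && ncol(tm$ntx)) {
    acc <- numeric(tm$n)
    for (j in seq_len(ncol(tm$ntx))) {
      ncp <- ((tm$ntx[, j] - tm$targ[, 1])^2 +
                (tm$nty[, j] - tm$targ[, 2])^2) / s2
      pj <- stats::pchisq(tm$d^2 / s2, df = 2, ncp = ncp)
      pj[is.na(ncp)] <- 0
      acc <- acc + pj
    }
    p <- p + params$beta * acc / pmax(tm$m, 1)
  }
  if (params$gamma > 0) {
    areas <- tm$areas
    if (is.null(areas))  # parameter-free, so cached by the fitting path
      areas <- vapply(seq_len(tm$n), function(i)
        disc_rect_area(tm$targ[i, ], tm$d[i], screen), numeric(1))
    p <- p + params$gamma * areas / screen$area
  }
  p
}

## Area of the intersection of a disc with the screen rectangle, by
## angular quadrature of the clipped polar radius (exact when the disc is
## fully inside: the midpoint rule integrates the constant exactly).
disc_rect_area <- function(center, radius, screen, n_theta = 1440) {
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  ct <- cos(theta); st <- sin(theta)
  rmax <- rep(radius, n_theta)
  tx <- ifelse(ct > 0, (screen$width - center[1]) / ct,
               ifelse(ct < 0, -center[1] / ct, Inf))
  ty <- ifelse(st > 0, (screen$height - center[2]) / st,
               ifelse(st < 0, -center[2] / st, Inf))
  rmax <- pmin(rmax, tx, ty)
  rmax <- pmax(rmax, 0)
  sum(0.5 * rmax^2) * 2 * pi / n_theta
}

## polar-grid integral of the full mixture density over the on-screen
## disc of radius d around the target
p_reject_quadrature <- function(tm, params, model, screen,
                                n_r = 64, n_theta = 128) {
  vapply(seq_len(tm$n), function(i) {
    d <- tm$d[i]
    ## Simpson weights in radius, midpoint in angle
    r <- seq(0, d, length.out = n_r + 1)
    wr <- simpson_weights(n_r + 1) * (d / n_r)
    theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
    px <- tm$targ[i, 1] + outer(r, cos(theta))
    py <- tm$targ[i, 2] + outer(r, sin(theta))
    pts <- cbind(as.numeric(px), as.numeric(py))
    keep <- on_screen(pts, screen)
    nt_cols <- which(!is.na(tm$ntx[i, ]))
    trial <- data.frame(resp_x = pts[, 1], resp_y = pts[, 2],
                        targ_x = tm$targ[i, 1], targ_y = tm$targ[i, 2])
    for (j in seq_along(nt_cols)) {
      trial[[paste0("nt", j, "_x")]] <- tm$ntx[i, nt_cols[j]]
      trial[[paste0("nt", j, "_y")]] <- tm$nty[i, nt_cols[j]]
    }
    dens <- suppressWarnings(mixture_density(trial, params, model, screen))
    dens[!keep] <- 0
    integrand <- matrix(dens * as.numeric(matrix(r, n_r + 1, n_theta)),
                        n_r + 1, n_theta)
    sum(wr * rowSums(integrand)) * 2 * pi / n_theta
  }, numeric(1))
}

simpson_weights <- function(n_points) {
  stopifnot(n_points %% 2 == 1)
  w <- rep(c(2, 4), length.out = n_points)
  w[1] <- w[n_points] <- 1
  w / 3
}

#' @rdname p_reject
#' @param epsilon Probabilities are clipped to `[epsilon, 1 - epsilon]`
#'   before taking logs.
#' @export
loglik_2afc <- function(data, params, screen = screen_geometry(),
                        model = wm_model("standard2afc"),
                        epsilon = 1e-9) {
  tm <- cd_matrices(data)
  if (any(is.na(tm$response)))
    stop("change-detection likelihood requires a `response` column (1 = ",
         "rejected as changed, 0 = accepted as unchanged)")
  p <- p_reject_analytic(tm, as_mixture_params(params), as_screen(screen))
  if (any(p <= 0 | p >= 1))
    warning("rejection probabilities of exactly 0 or 1 clipped to epsilon")
  loglik_2afc_from_p(p, tm$response, epsilon)
}

loglik_2afc_from_p <- function(p, response, epsilon = 1e-9) {
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  sum(response * log(p) + (1 - response) * log(1 - p))
}

## internal path used by fit_mle (no re-extraction, silent clipping)
loglik_2afc_tm <- function(tm, params, model, screen) {
  p <- p_reject_analytic(tm, params, screen)
  loglik_2afc_from_p(p, tm$response)
}

#' Simulate change-detection trials
#'
#' Places stimuli per the design, displaces the probe from the target by a
#' distance drawn uniformly from `probe_distance` in a uniform direction
#' (redrawn until the probe is on-screen), simulates a continuous response
#' from the mixture, and records a rejection (`response = 1`) when that
#' response lies closer to the target than the probe does — the generative
#' process whose likelihood [loglik_2afc()] computes.
#'
#' @inheritParams simulate_responses
#' @param probe_distance Range of probe displacements (length units).
#' @return A tibble of change-detection trials.
#' @export
simulate_change_detection <- function(params, design = task_design(),
                                      probe_distance = c(10, 400)) {
  params <- as_mixture_params(params)
  stimuli <- generate_stimuli(design)
  scr <- design$screen
  n <- nrow(stimuli)
  targ <- cbind(stimuli$targ_x, stimuli$targ_y)
  probe <- matrix(NA_real_, n, 2)
  d <- stats::runif(n, probe_distance[1], probe_distance[2])
  todo <- seq_len(n)
  while (length(todo)) {
    ang <- stats::runif(length(todo), 0, 2 * pi)
    cand <- targ[todo, , drop = FALSE] +
      d[todo] * cbind(cos(ang), sin(ang))
    ok <- on_screen(cand, scr)
    probe[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  resp <- simulate_responses(params, design, stimuli = stimuli)
  rdist <- sqrt((resp$resp_x - stimuli$targ_x)^2 +
                  (resp$resp_y - stimuli$targ_y)^2)
  out <- tibble::tibble(probe_x = probe[, 1], probe_y = probe[, 2],
                        response = as.integer(rdist < d))
  tibble::as_tibble(cbind(out, stimuli))
}
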