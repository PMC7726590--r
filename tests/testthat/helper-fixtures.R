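# Shared fixtures built in code.

default_screen <- screen_geometry(1366, 768)

# A dataset with fixed, hand-chosen geometry (no randomness): n trials on
# the default screen, target and two nontargets well inside the screen.
fixed_trials <- function(n = 20, resp_jitter = 0) {
  set.seed(99)
  tibble::tibble(
    resp_x = seq(200, 1100, length.out = n) + resp_jitter,
    resp_y = seq(150, 600, length.out = n),
    targ_x = rep(c(400, 800), length.out = n),
    targ_y = rep(c(300, 500), length.out = n),
    nt1_x = rep(c(600, 300), length.out = n),
    nt1_y = rep(c(200, 600), length.out = n),
    nt2_x = rep(c(1000, 900), length.out = n),
    nt2_y = rep(c(650, 150), length.out = n))
}

# Independent brute-force oracle for the 2D misbinding density: explicit
# per-trial loop over components, no shared code with the implementation.
oracle_density_2d <- function(data, beta, gamma, sigma, width = 1366,
                              height = 768) {
  alpha <- 1 - beta - gamma
  vapply(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    g2 <- function(dx, dy)
      exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
    dens <- alpha * g2(row$resp_x - row$targ_x, row$resp_y - row$targ_y)
    nts <- list()
    j <- 1
    while (!is.null(row[[paste0("nt", j, "_x")]])) {
      if (!is.na(row[[paste0("nt", j, "_x")]]))
        nts[[length(nts) + 1]] <- c(row[[paste0("nt", j, "_x")]],
                                    row[[paste0("nt", j, "_y")]])
      j <- j + 1
      if (!paste0("nt", j, "_x") %in% names(row)) break
    }
    if (length(nts))
      dens <- dens + beta * mean(vapply(nts, function(nt)
        g2(row$resp_x - nt[1], row$resp_y - nt[2]), numeric(1)))
    dens + gamma / (width * height)
  }, numeric(1))
}

# 2D Simpson quadrature of a mixture density over the screen.
integrate_density_2d <- function(data_row, params, screen, model = NULL,
                                 n_grid = 200) {
  xs <- seq(0, screen$width, length.out = n_grid + 1)
  ys <- seq(0, screen$height, length.out = n_grid + 1)
  wx <- simpson_w(n_grid + 1) * (screen$width / n_grid)
  wy <- simpson_w(n_grid + 1) * (screen$height / n_grid)
  grid <- expand.grid(resp_x = xs, resp_y = ys)
  d <- data_row[rep(1, nrow(grid)), , drop = FALSE]
  d$resp_x <- grid$resp_x
  d$resp_y <- grid$resp_y
  dens <- if (is.null(model)) density_2d(d, params, screen)
  else locmix:::mixture_density(d, params, model, screen)
  m <- matrix(dens, n_grid + 1, n_grid + 1)
  as.numeric(t(wx) %*% m %*% wy)
}

simpson_w <- function(n_points) {
  w <- rep(c(2, 4), length.out = n_points)
  w[1] <- w[n_points] <- 1
  w / 3
}
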