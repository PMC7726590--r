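scr <- default_screen

test_that("2D density matches closed forms for pure components", {
  d <- tibble::tibble(resp_x = 500, resp_y = 400, targ_x = 500,
                      targ_y = 400, nt1_x = 900, nt1_y = 200)
  # pure guessing: uniform over the screen area
  expect_equal(density_2d(d, mixture_params(gamma = 1, sigma = 30), scr),
               1 / (1366 * 768))
  # pure target responding at the mode of the bivariate Gaussian
  expect_equal(density_2d(d, mixture_params(gamma = 0, sigma = 30), scr),
               1 / (2 * pi * 30^2))
  # mixture of the two closed forms
  expect_equal(density_2d(d, mixture_params(gamma = 0.5, sigma = 30), scr),
               0.5 / (2 * pi * 900) + 0.5 / (1366 * 768))
})

test_that("2D density matches an independent brute-force oracle", {
  data <- fixed_trials(20)
  for (p in list(c(.2, .3, 25), c(0, .9, 60), c(.5, .1, 5))) {
    expect_equal(
      density_2d(data, mixture_params(beta = p[1], gamma = p[2],
                                      sigma = p[3]), scr),
      oracle_density_2d(data, p[1], p[2], p[3]),
      tolerance = 1e-12)
  }
})

test_that("1D density has the von Mises closed forms", {
  d <- tibble::tibble(resp = 0.3, targ = 0.3, nt1 = -2)
  expect_equal(density_1d(d, mixture_params(gamma = 1, kappa = 1)),
               1 / (2 * pi))
  # kappa -> 0 limit is uniform
  expect_equal(density_1d(d, mixture_params(gamma = 0, kappa = 1e-14)),
               1 / (2 * pi), tolerance = 1e-6)
  # mode height of the von Mises: exp(kappa) / (2 pi I0(kappa))
  expect_equal(density_1d(d, mixture_params(gamma = 0, kappa = 2)),
               exp(2) / (2 * pi * besselI(2, 0)), tolerance = 1e-12)
})

test_that("densities integrate to one (quadrature oracles)", {
  # 2D: all items >= 5 sigma from every edge
  row <- tibble::tibble(resp_x = 0, resp_y = 0, targ_x = 600, targ_y = 400,
                        nt1_x = 500, nt1_y = 300)
  p <- mixture_params(beta = 0.3, gamma = 0.2, sigma = 40)
  expect_equal(integrate_density_2d(row, p, scr), 1, tolerance = 1e-4)
  # truncated mode integrates to one even with items near an edge
  row_edge <- tibble::tibble(resp_x = 0, resp_y = 0, targ_x = 30,
                             targ_y = 40, nt1_x = 1350, nt1_y = 700)
  model_tr <- wm_model("misbind2d", truncated = TRUE)
  expect_equal(integrate_density_2d(row_edge, p, scr, model = model_tr),
               1, tolerance = 1e-4)
  # untruncated near the edge loses exactly the off-screen Gaussian mass
  mass_t <- locmix:::gauss2_screen_mass(cbind(30, 40), 40, scr)
  mass_n <- locmix:::gauss2_screen_mass(cbind(1350, 700), 40, scr)
  expect_equal(integrate_density_2d(row_edge, p, scr),
               p$alpha * mass_t + p$beta * mass_n + p$gamma,
               tolerance = 1e-4)
  # 1D integrates to 1 over the circle for several parameter settings
  theta <- seq(-pi, pi, length.out = 2001)
  w <- simpson_w(2001) * (2 * pi / 2000)
  for (pars in list(c(.3, .3, 2), c(0, 1, 1), c(.8, .1, 20))) {
    d1 <- tibble::tibble(resp = theta, targ = 0.5, nt1 = -1.2)
    dens <- density_1d(d1, mixture_params(beta = pars[1], gamma = pars[2],
                                          kappa = pars[3]))
    expect_equal(sum(w * dens), 1, tolerance = 1e-6)
  }
})

test_that("2D density is invariant under rigid translation of the scene", {
  data <- fixed_trials(10)
  p <- mixture_params(beta = 0.25, gamma = 0.25, sigma = 20)
  base <- density_2d(data, p, scr)
  shifted <- data
  for (col in grep("_x$", names(data), value = TRUE))
    shifted[[col]] <- shifted[[col]] + 57
  for (col in grep("_y$", names(data), value = TRUE))
    shifted[[col]] <- shifted[[col]] - 33
  expect_equal(density_2d(shifted, p, scr), base, tolerance = 1e-12)
})

test_that("log-likelihood sums per-trial logs and is additive", {
  # two pure-guess trials
  d <- tibble::tibble(resp_x = c(10, 1200), resp_y = c(10, 700),
                      targ_x = 500, targ_y = 300)
  ll <- log_likelihood(d, mixture_params(gamma = 1, sigma = 30),
                       wm_model("standard2d"), scr)
  expect_equal(ll, 2 * log(1 / (1366 * 768)), tolerance = 1e-12)

  data <- fixed_trials(20)
  p <- mixture_params(beta = 0.3, gamma = 0.2, sigma = 30)
  m <- wm_model("misbind2d")
  full <- log_likelihood(data, p, m, scr)
  expect_equal(full,
               log_likelihood(data[1:7, ], p, m, scr) +
                 log_likelihood(data[8:20, ], p, m, scr))
  # invariant to permuting nontarget order within trials
  swapped <- data
  swapped$nt1_x <- data$nt2_x; swapped$nt1_y <- data$nt2_y
  swapped$nt2_x <- data$nt1_x; swapped$nt2_y <- data$nt1_y
  expect_equal(log_likelihood(swapped, p, m, scr), full)
  # brute-force oracle agreement
  expect_equal(full, sum(log(oracle_density_2d(data, 0.3, 0.2, 30))),
               tolerance = 1e-10)
})

test_that("trials without nontargets drop the misbinding term with warning", {
  d <- tibble::tibble(resp_x = c(500, 700), resp_y = c(400, 300),
                      targ_x = 500, targ_y = 400,
                      nt1_x = c(900, NA), nt1_y = c(200, NA))
  p <- mixture_params(beta = 0.4, gamma = 0.1, sigma = 30)
  expect_warning(dens <- density_2d(d, p, scr), "no nontargets")
  # second trial: only alpha and gamma terms remain
  expect_equal(dens[2],
               0.5 * locmix:::gauss2_sqd((700 - 500)^2 + (300 - 400)^2, 30) +
                 0.1 / scr$area)
})

test_that("BIC follows k ln n - 2 lnL and the nested-model identity", {
  expect_equal(bic(-500, 3, 100), 3 * log(100) + 1000)
  expect_equal(bic(-500, 0, 77), 1000)
  # nested models on the same data
  d1 <- bic(-480, 4, 100) - bic(-500, 3, 100)
  expect_equal(d1, -2 * (-480 - (-500)) + (4 - 3) * log(100))
})

test_that("kappa-to-SD conversion matches a Monte-Carlo oracle", {
  expect_error(kappa_to_sd(-1), "non-negative")
  expect_equal(kappa_to_sd(0), sqrt(pi^2 / 3))  # documented uniform cap
  expect_lt(kappa_to_sd(200), 0.08)             # large kappa -> small SD
  expect_true(all(diff(kappa_to_sd(c(0.5, 1, 2, 5, 10))) < 0))
  set.seed(123)
  th <- locmix:::rvonmises(1e6, 2)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_equal(kappa_to_sd(2), sqrt(-2 * log(rbar)), tolerance = 2e-3)
  # inversion round-trip
  expect_equal(sd_to_kappa(kappa_to_sd(c(0.7, 2, 8))), c(0.7, 2, 8),
               tolerance = 1e-6)
})

test_that("two-class density reduces to the single-class model", {
  set.seed(5)
  data <- fixed_trials(20)
  data$nt1_class <- 1
  data$nt2_class <- 2
  # equal class weights with one nontarget per class equals pooled beta
  p2 <- mixture_params(beta1 = 0.15, beta2 = 0.15, gamma = 0.2, sigma = 30)
  p1 <- mixture_params(beta = 0.3, gamma = 0.2, sigma = 30)
  expect_equal(density_2d_two_class(data, p2, scr),
               density_2d(data, p1, scr), tolerance = 1e-12)
  # gamma = 1: class structure irrelevant
  pg <- mixture_params(beta1 = 0, beta2 = 0, gamma = 1, sigma = 30)
  expect_equal(density_2d_two_class(data, pg, scr),
               rep(1 / scr$area, nrow(data)))
  # beta2 = 0 equals the single-class model restricted to class-1 nontargets
  pz <- mixture_params(beta1 = 0.3, beta2 = 0, gamma = 0.2, sigma = 30)
  only1 <- data[, c("resp_x", "resp_y", "targ_x", "targ_y",
                    "nt1_x", "nt1_y")]
  expect_equal(density_2d_two_class(data, pz, scr),
               density_2d(only1, p1, scr), tolerance = 1e-12)
})

test_that("non-finite inputs are rejected", {
  d <- tibble::tibble(resp_x = NaN, resp_y = 1, targ_x = 5, targ_y = 5)
  expect_error(density_2d(d, mixture_params(gamma = 1, sigma = 1), scr),
               "non-finite")
})
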