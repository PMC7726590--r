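scr <- default_screen

test_that("MLE recovers generating parameters at a central cell", {
  set.seed(20)
  true <- mixture_params(beta = .3, gamma = .3, sigma = 30)
  errs <- t(replicate(20, {
    d <- simulate_responses(true)
    f <- fit_mle(d, wm_model("misbind2d"), scr)
    c(beta = f$params$beta - .3, gamma = f$params$gamma - .3,
      sigma = f$params$sigma - 30)
  }))
  expect_lt(abs(median(errs[, "beta"])), 0.08)
  expect_lt(abs(median(errs[, "gamma"])), 0.08)
  expect_lt(abs(median(errs[, "sigma"])), 5)
})

test_that("pure-guess data recovers a high guess rate", {
  set.seed(21)
  d <- simulate_responses(mixture_params(gamma = 1, sigma = 30),
                          task_design(n_trials = 500))
  f <- fit_mle(d, wm_model("misbind2d"), scr)
  expect_gt(f$params$gamma, 0.9)
})

test_that("the MLE log-likelihood dominates the true parameters", {
  set.seed(22)
  true <- mixture_params(beta = .2, gamma = .4, sigma = 50)
  m <- wm_model("misbind2d")
  for (i in 1:5) {
    d <- simulate_responses(true)
    f <- fit_mle(d, m, scr)
    expect_gte(f$loglik + 1e-6, log_likelihood(d, true, m, scr))
  }
})

test_that("BIC selects the generating model in most replicates", {
  set.seed(23)
  hits_misbind <- hits_standard <- 0
  n_rep <- 25
  for (i in seq_len(n_rep)) {
    d1 <- simulate_responses(mixture_params(beta = .3, gamma = .2,
                                            sigma = 30))
    d0 <- simulate_responses(mixture_params(beta = 0, gamma = .2,
                                            sigma = 30))
    b1 <- fit_mle(d1, wm_model("misbind2d"), scr)$bic <
      fit_mle(d1, wm_model("standard2d"), scr)$bic
    b0 <- fit_mle(d0, wm_model("standard2d"), scr)$bic <
      fit_mle(d0, wm_model("misbind2d"), scr)$bic
    hits_misbind <- hits_misbind + b1
    hits_standard <- hits_standard + b0
  }
  expect_gte(hits_misbind / n_rep, 0.8)
  expect_gte(hits_standard / n_rep, 0.8)
})

test_that("fitting requires more trials than parameters", {
  d <- fixed_trials(3)
  expect_error(fit_mle(d[1:2, ], wm_model("misbind2d"), scr), "trials")
})

test_that("the two-class model fits its own simulated task", {
  set.seed(24)
  p <- mixture_params(beta1 = .25, beta2 = .1, gamma = .15, sigma = 30)
  d <- simulate_ignore_update(p, n_trials = 300)
  f <- suppressWarnings(fit_mle(d, wm_model("misbind2class"), scr))
  expect_true(f$convergence)
  expect_lt(abs(f$params$beta1 - .25), 0.12)
  expect_equal(f$params$sigma, 30, tolerance = 0.2)
  expect_equal(f$k, 4)
})

test_that("cross-validation prefers the generating model on average", {
  set.seed(25)
  d <- simulate_responses(mixture_params(beta = .45, gamma = .1,
                                         sigma = 25),
                          task_design(n_trials = 200))
  cv <- crossval_response_sampling(
    d, models = list(misbind = wm_model("misbind2d"),
                     standard = wm_model("standard2d")),
    screen = scr, reps = 20)
  expect_gte(cv$mean_heldout[cv$model == "misbind"],
             cv$mean_heldout[cv$model == "standard"])
})

test_that("cross-validation is reproducible under a fixed seed", {
  d <- local({
    set.seed(26)
    simulate_responses(mixture_params(beta = .2, gamma = .3, sigma = 30),
                       task_design(n_trials = 60))
  })
  run <- function() {
    set.seed(123)
    crossval_response_sampling(d, models = list(u = wm_model("misbind2d")),
                               screen = scr, reps = 3)
  }
  expect_identical(run(), run())
})

test_that("KDE guesses do not inflate held-out likelihood on uniform data", {
  set.seed(27)
  d <- simulate_responses(mixture_params(beta = .1, gamma = .5, sigma = 30),
                          task_design(n_trials = 150))
  cv <- crossval_response_sampling(d, screen = scr, reps = 15)
  ratio <- cv$mean_heldout[cv$model == "kde"] /
    cv$mean_heldout[cv$model == "uniform"]
  expect_lt(abs(ratio - 1), 0.25)
})

test_that("condition comparison behaves as a calibrated Wald test", {
  set.seed(28)
  d <- simulate_responses(mixture_params(beta = .3, gamma = .3, sigma = 30))
  fa <- fit_mle(d, wm_model("misbind2d"), scr, hessian = TRUE)
  same <- condition_compare(fa, fa)
  expect_lt(same$statistic, 1e-6)
  expect_gt(same$p_value, 0.999)
  expect_equal(same$df, 3)

  # power: well-separated conditions are usually distinguished
  rej_power <- mean(replicate(10, {
    a <- fit_mle(simulate_responses(mixture_params(beta = .1, gamma = .1,
                                                   sigma = 20)),
                 wm_model("misbind2d"), scr, hessian = TRUE)
    b <- fit_mle(simulate_responses(mixture_params(beta = .4, gamma = .4,
                                                   sigma = 60)),
                 wm_model("misbind2d"), scr, hessian = TRUE)
    condition_compare(a, b)$p_value <= 0.05
  }))
  expect_gte(rej_power, 0.8)

  # type I: identical conditions are rarely distinguished
  rej_null <- mean(replicate(15, {
    a <- fit_mle(simulate_responses(mixture_params(beta = .3, gamma = .3,
                                                   sigma = 30)),
                 wm_model("misbind2d"), scr, hessian = TRUE)
    b <- fit_mle(simulate_responses(mixture_params(beta = .3, gamma = .3,
                                                   sigma = 30)),
                 wm_model("misbind2d"), scr, hessian = TRUE)
    condition_compare(a, b)$p_value <= 0.05
  }))
  expect_lte(rej_null, 0.34)
})
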