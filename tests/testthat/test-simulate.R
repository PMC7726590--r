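scr <- default_screen

test_that("constrained stimulus placement honours all spacing rules", {
  set.seed(2)
  design <- constrained_design(n_trials = 1e4)
  st <- generate_stimuli(design)
  xs <- cbind(st$targ_x, st$nt1_x, st$nt2_x)
  ys <- cbind(st$targ_y, st$nt1_y, st$nt2_y)
  # pairwise distances >= 88
  for (i in 1:2) for (j in (i + 1):3)
    expect_true(all((xs[, i] - xs[, j])^2 + (ys[, i] - ys[, j])^2 >= 88^2))
  # centre distance >= 88, edge margins >= 29
  for (i in 1:3) {
    expect_true(all((xs[, i] - 683)^2 + (ys[, i] - 384)^2 >= 88^2))
    expect_true(all(xs[, i] >= 29 & xs[, i] <= 1366 - 29))
    expect_true(all(ys[, i] >= 29 & ys[, i] <= 768 - 29))
  }
})

test_that("unconstrained placement is uniform over the screen", {
  set.seed(3)
  st <- generate_stimuli(task_design(n_trials = 1e4, n_items = 1))
  # CLT bounds around the screen centre
  expect_equal(mean(st$targ_x), 683, tolerance = 3 * (1366 / sqrt(12)) /
                 sqrt(1e4) / 683)
  expect_equal(mean(st$targ_y), 384, tolerance = 3 * (768 / sqrt(12)) /
                 sqrt(1e4) / 384)
})

test_that("single-item designs and infeasible constraints behave sanely", {
  set.seed(4)
  st <- generate_stimuli(task_design(n_trials = 10, n_items = 1,
                                     min_item_distance = 500))
  expect_equal(nrow(st), 10)  # pairwise constraint vacuous with one item
  expect_error(generate_stimuli(
    task_design(n_trials = 5, n_items = 10, min_item_distance = 700,
                max_attempts = 100)), "min_item_distance")
  expect_error(task_design(min_edge_distance = 500), "feasible")
})

test_that("response types follow the mixture weights", {
  set.seed(5)
  d <- simulate_responses(mixture_params(beta = .3, gamma = .2, sigma = 30),
                          task_design(n_trials = 1e4))
  counts <- table(factor(d$resp_type,
                         levels = c("target", "nontarget", "guess")))
  expect_gt(stats::chisq.test(counts, p = c(.5, .3, .2))$p.value, 0.01)
  # misbinds split evenly between the two nontargets
  nt_rows <- d[d$resp_type == "nontarget", ]
  d1 <- (nt_rows$resp_x - nt_rows$nt1_x)^2 + (nt_rows$resp_y - nt_rows$nt1_y)^2
  d2 <- (nt_rows$resp_x - nt_rows$nt2_x)^2 + (nt_rows$resp_y - nt_rows$nt2_y)^2
  n1 <- sum(d1 < d2)
  expect_gt(stats::binom.test(n1, nrow(nt_rows), 0.5)$p.value, 0.001)
})

test_that("simulated responses never leave the screen", {
  set.seed(6)
  for (sigma in c(1, 50, 300)) {
    d <- simulate_responses(mixture_params(beta = .3, gamma = .3,
                                           sigma = sigma),
                            task_design(n_trials = 500))
    expect_true(all(d$resp_x >= 0 & d$resp_x <= 1366 &
                      d$resp_y >= 0 & d$resp_y <= 768))
  }
})

test_that("tiny imprecision concentrates responses on the target", {
  set.seed(7)
  d <- simulate_responses(mixture_params(sigma = 0.1),
                          task_design(n_trials = 1e4))
  dist <- sqrt((d$resp_x - d$targ_x)^2 + (d$resp_y - d$targ_y)^2)
  expect_gte(mean(dist < 1), 0.999)
})

test_that("pure guessing is uniform on each axis", {
  set.seed(8)
  d <- simulate_responses(mixture_params(gamma = 1, sigma = 30),
                          task_design(n_trials = 1e4))
  expect_gt(suppressWarnings(
    stats::ks.test(d$resp_x / 1366, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(d$resp_y / 768, "punif"))$p.value, 0.01)
})

test_that("seeded simulation is bit-reproducible", {
  run <- function() {
    set.seed(77)
    simulate_responses(mixture_params(beta = .2, gamma = .2, sigma = 40),
                       constrained_design(n_trials = 50))
  }
  expect_identical(run(), run())
})

test_that("the sweep grid matches the canonical ranges and filter", {
  cells <- sweep_grid()
  expect_equal(sort(unique(cells$sigma)), seq(0.1, 100, length.out = 11))
  g <- sort(unique(cells$gamma))
  expect_equal(range(g), c(0.01, 0.98))
  expect_equal(diff(g)[1], (0.98 - 0.01) / 10, tolerance = 1e-12)
  expect_true(all(cells$gamma + cells$beta <= 1))
  expect_equal(cells$alpha, 1 - cells$gamma - cells$beta)
  # 66 feasible (gamma, beta) pairs x 11 sigma values
  expect_equal(nrow(cells), 66 * 11)
})

test_that("simulate_sweep yields one dataset per cell and iteration", {
  set.seed(9)
  cells <- sweep_grid(n_values = 3)
  sw <- simulate_sweep(cells, task_design(n_trials = 10), iterations = 2)
  expect_length(sw, 2 * nrow(cells))
  expect_true(all(vapply(sw, function(s) nrow(s$data) == 10, logical(1))))
})

test_that("the von Mises sampler has the right resultant length", {
  set.seed(10)
  for (kappa in c(0.5, 4)) {
    th <- locmix:::rvonmises(2e5, kappa)
    rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    expect_lt(abs(rbar - besselI(kappa, 1, TRUE) / besselI(kappa, 0, TRUE)),
              0.008)  # ~3 standard errors at this sample size
  }
  # circular mean at zero
  th <- locmix:::rvonmises(2e5, 3)
  expect_lt(abs(atan2(mean(sin(th)), mean(cos(th)))), 0.02)
})

test_that("1D simulation respects the circular domain and weights", {
  set.seed(11)
  d <- simulate_responses_1d(mixture_params(beta = .3, gamma = .3,
                                            kappa = 8), n_trials = 5000)
  expect_true(all(d$resp >= -pi & d$resp < pi))
  counts <- table(factor(d$resp_type,
                         levels = c("target", "nontarget", "guess")))
  expect_gt(stats::chisq.test(counts, p = c(.4, .3, .3))$p.value, 0.01)
})
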