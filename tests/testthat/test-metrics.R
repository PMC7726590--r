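scr <- default_screen

test_that("target and nearest-neighbour distances follow their geometry", {
  d <- tibble::tibble(resp_x = 103, resp_y = 104, targ_x = 100,
                      targ_y = 100, nt1_x = 103, nt1_y = 104)
  expect_equal(target_distance(d), 5)  # 3-4-5 triangle
  expect_equal(nearest_neighbor_distance(d), 0)  # response on a nontarget
  d2 <- tibble::tibble(resp_x = 50, resp_y = 50, targ_x = 50, targ_y = 50)
  expect_equal(target_distance(d2), 0)
  expect_equal(nearest_neighbor_distance(d2), 0)  # single item reduces

  set.seed(50)
  data <- simulate_responses(mixture_params(beta = .3, gamma = .3,
                                            sigma = 40))
  td <- target_distance(data)
  nn <- nearest_neighbor_distance(data)
  expect_true(all(nn <= td & nn >= 0))
  # independent oracle
  oracle <- vapply(seq_len(nrow(data)), function(i) {
    r <- c(data$resp_x[i], data$resp_y[i])
    min(sqrt(sum((r - c(data$targ_x[i], data$targ_y[i]))^2)),
        sqrt(sum((r - c(data$nt1_x[i], data$nt1_y[i]))^2)),
        sqrt(sum((r - c(data$nt2_x[i], data$nt2_y[i]))^2)))
  }, numeric(1))
  expect_equal(nn, oracle, tolerance = 1e-12)
})

test_that("swap errors count near-nontarget responses and correct for chance", {
  # response exactly on a nontarget counts as a swap at any threshold
  d <- tibble::tibble(resp_x = 900, resp_y = 200, targ_x = 400,
                      targ_y = 300, nt1_x = 900, nt1_y = 200)
  expect_equal(swap_errors(d, scr, threshold = 10,
                           chance_corrected = FALSE), 1)
  # nontargets far beyond target distance + threshold: correction is zero
  d2 <- tibble::tibble(resp_x = c(420, 380), resp_y = c(310, 290),
                       targ_x = 400, targ_y = 300,
                       nt1_x = 1300, nt1_y = 700)
  expect_equal(swap_errors(d2, scr, threshold = 30, chance_corrected = TRUE),
               swap_errors(d2, scr, threshold = 30, chance_corrected = FALSE))
  # corrected never exceeds uncorrected
  set.seed(51)
  data <- simulate_responses(mixture_params(beta = .3, gamma = .3,
                                            sigma = 60))
  expect_lte(swap_errors(data, scr), swap_errors(data, scr,
                                                 chance_corrected = FALSE))
  # no nontargets: undefined
  d3 <- tibble::tibble(resp_x = 1, resp_y = 1, targ_x = 2, targ_y = 2)
  expect_warning(out <- swap_errors(d3, scr), "undefined")
  expect_true(is.na(out))
})

test_that("the chance correction matches a Monte-Carlo circle oracle", {
  set.seed(52)
  data <- simulate_responses(mixture_params(beta = .2, gamma = .3,
                                            sigma = 80),
                             task_design(n_trials = 50))
  thr <- degrees_to_px(1.5)
  uncorrected <- swap_errors(data, scr, thr, chance_corrected = FALSE)
  corrected <- swap_errors(data, scr, thr, chance_corrected = TRUE)
  r <- target_distance(data)
  mc_corr <- vapply(seq_len(nrow(data)), function(i) {
    ang <- runif(2e4, 0, 2 * pi)
    cx <- data$targ_x[i] + r[i] * cos(ang)
    cy <- data$targ_y[i] + r[i] * sin(ang)
    keep <- cx >= 0 & cx <= 1366 & cy >= 0 & cy <= 768
    if (!any(keep)) return(0)
    near <- (cx[keep] - data$nt1_x[i])^2 + (cy[keep] - data$nt1_y[i])^2 <
      thr^2 |
      (cx[keep] - data$nt2_x[i])^2 + (cy[keep] - data$nt2_y[i])^2 < thr^2
    mean(near)
  }, numeric(1))
  expect_lt(abs((uncorrected - mean(mc_corr)) - corrected), 1e-2)
})

test_that("mean-threshold swap errors scale with the data", {
  # all responses on target: threshold and swaps are zero
  d <- tibble::tibble(resp_x = c(100, 200), resp_y = c(100, 200),
                      targ_x = c(100, 200), targ_y = c(100, 200),
                      nt1_x = c(500, 600), nt1_y = c(500, 600))
  expect_equal(swap_errors_mean_threshold(d, scr), 0)
  # scale invariance: multiplying all coordinates by c leaves it unchanged
  set.seed(53)
  data <- simulate_responses(mixture_params(beta = .3, gamma = .2,
                                            sigma = 50))
  scaled <- data
  for (col in grep("_(x|y)$", names(data), value = TRUE))
    scaled[[col]] <- scaled[[col]] * 2
  big <- screen_geometry(2 * 1366, 2 * 768)
  expect_equal(swap_errors_mean_threshold(scaled, big),
               swap_errors_mean_threshold(data, scr), tolerance = 1e-12)
  # equals the fixed-threshold routine at the same threshold
  thr <- mean(target_distance(data))
  expect_equal(swap_errors_mean_threshold(data, scr),
               swap_errors(data, scr, threshold = thr))
})

test_that("split-half reliability is 1 for stable measures, ~0 for noise", {
  set.seed(54)
  datasets <- lapply(seq(10, 100, by = 10), function(mu)
    simulate_responses(mixture_params(gamma = .1, sigma = mu),
                       task_design(n_trials = 40)))
  # a participant-constant measure is perfectly reliable
  datasets_id <- lapply(1:8, function(i) {
    d <- datasets[[i]]; d$id_value <- i; d
  })
  expect_equal(split_half_reliability(datasets_id,
                                      function(d) d$id_value[1], 10), 1)
  # independent noise has reliability near zero
  noise <- function(d) rnorm(1)
  expect_lt(abs(split_half_reliability(datasets, noise, 200)), 0.15)
  # mean target distance separates heterogeneous simulated participants
  rel_td <- split_half_reliability(datasets,
                                   function(d) mean(target_distance(d)), 50)
  expect_gt(rel_td, 0.6)
})
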