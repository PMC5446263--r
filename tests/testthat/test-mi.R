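test_that("input_entropy matches the textbook values", {
  expect_equal(input_entropy(8), 3)
  expect_equal(input_entropy(2), 1)
  expect_equal(input_entropy(1), 0)
  expect_equal(input_entropy(4, c(0.5, 0.5, 0, 0)), 1)
  expect_error(input_entropy(2.5), "integer")
  expect_error(input_entropy(3, c(0.5, 0.5)), "probability")
  expect_error(input_entropy(2, c(0.7, 0.7)), "probability")
})

test_that("a noiseless 8-level channel attains the 3-bit input entropy", {
  df <- tibble::tibble(stimulus_index = rep(1:8, each = 50),
                       response = rep(1:8, each = 50) * 1.7)
  est <- estimate_mi(df, n_boot = 50)
  expect_equal(est$mi_bits, 3, tolerance = 0.05)
  expect_equal(est$mi_bits_bc, 3, tolerance = 0.05)
  expect_equal(est$input_entropy_bits, 3)
  expect_lte(est$ci_upper, 3 + 1e-9)  # clamped to the input entropy
})

test_that("an independent response carries ~0 bits after bias correction", {
  set.seed(3)
  df <- tibble::tibble(stimulus_index = rep(1:4, each = 1000),
                       response = rnorm(4000))
  est <- estimate_mi(df, n_boot = 0)
  expect_lt(abs(est$mi_bits_bc), 0.05)
  # the raw plug-in is biased upward; correction must shrink it
  expect_lt(est$mi_bits_bc, est$mi_bits)
})

test_that("estimate_mi matches the Gaussian-mixture quadrature oracle", {
  df <- gauss_channel_samples()
  oracle <- gauss_channel_mi_oracle()
  est <- estimate_mi(df, bins = 16, n_boot = 0)
  expect_equal(est$mi_bits_bc, oracle, tolerance = 0.05)
  knn <- estimate_mi(df, method = "knn", n_boot = 0)
  expect_equal(knn$mi_bits, oracle, tolerance = 0.08)
})

test_that("MI estimates respect their information-theoretic bounds", {
  set.seed(9)
  for (i in 1:5) {
    df <- tibble::tibble(
      stimulus_index = rep(1:3, each = 60),
      response = rnorm(180, mean = rep(c(0, runif(1, 0, 3), runif(1, 0, 6)),
                                       each = 60)))
    est <- estimate_mi(df, bins = 8, n_boot = 0)
    expect_gte(est$mi_bits_bc, 0)
    expect_lte(est$mi_bits_bc, est$input_entropy_bits)
    expect_lte(est$mi_bits, log2(8) + 1e-9)
  }
})

test_that("MI degrades monotonically with measurement noise (same seed)", {
  set.seed(21)
  z <- rnorm(4 * 500)
  mi_at <- function(sd) {
    df <- tibble::tibble(stimulus_index = rep(1:4, each = 500),
                         response = rep(c(0, 1, 2, 3), each = 500) + sd * z)
    estimate_mi(df, n_boot = 0)$mi_bits_bc
  }
  mis <- vapply(c(0.3, 1, 3), mi_at, numeric(1))
  expect_true(all(diff(mis) < 0))
})

test_that("data-processing inequality holds along a simulated chain", {
  set.seed(5)
  s <- rep(1:4, each = 800)
  upstream <- s + rnorm(length(s), sd = 0.6)
  downstream <- upstream + rnorm(length(s), sd = 0.6)
  mi_up <- estimate_mi(tibble::tibble(stimulus_index = s, response = upstream),
                       n_boot = 0)$mi_bits_bc
  mi_down <- estimate_mi(tibble::tibble(stimulus_index = s, response = downstream),
                         n_boot = 0)$mi_bits_bc
  expect_lte(mi_down, mi_up + 0.05)
})

test_that("bias-corrected MI converges to the entropy on a near-noiseless channel", {
  errs <- vapply(c(50, 200, 1000), function(n) {
    set.seed(n)
    df <- tibble::tibble(stimulus_index = rep(1:8, each = n),
                         response = rep(1:8, each = n) +
                           rnorm(8 * n, sd = 0.05))
    abs(estimate_mi(df, n_boot = 0)$mi_bits_bc - 3)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.02)
  expect_lt(errs[3], 0.02)
})

test_that("estimate_mi rejects insufficient samples, naming the level", {
  df <- tibble::tibble(stimulus_index = c(rep(1, 50), rep(2, 5)),
                       response = rnorm(55))
  expect_error(estimate_mi(df), "2")
  expect_error(estimate_mi(tibble::tibble(stimulus_index = rep(1, 50),
                                          response = rnorm(50))),
               "at least 2 stimulus levels")
  expect_error(estimate_mi(tibble::tibble(x = 1)), "stimulus_index")
})

test_that("simulate_population is reproducible and honors zero heterogeneity", {
  hill <- function(p, stimulus, readout_time) {
    p$Rtot * stimulus / (stimulus + 1e-9)
  }
  spec0 <- population_spec(c(1e-10, 1e-8), n_cells = 12, cv = 0,
                           noise_sd = 0, seed = 4)
  s0 <- simulate_population(network_params(), spec0, response_fn = hill)
  # zero CV, zero noise: every cell at a level responds identically
  per_level <- tapply(s0$response, s0$stimulus_index, function(v) diff(range(v)))
  expect_true(all(per_level == 0))
  spec1 <- population_spec(c(1e-10, 1e-8), n_cells = 12, cv = 0.3,
                           noise_sd = 0, seed = 4)
  s1 <- simulate_population(network_params(), spec1, response_fn = hill)
  s2 <- simulate_population(network_params(), spec1, response_fn = hill)
  expect_identical(s1$response, s2$response)  # seed fixes the full sample
  expect_gt(sd(s1$response[s1$stimulus_index == 2]), 0)
  # log-normal scaling: median close to the homogeneous response
  expect_equal(median(s1$response[s1$stimulus_index == 2]),
               s0$response[s0$stimulus_index == 2][1], tolerance = 0.25)
})

test_that("population heterogeneity and adaptation reproduce the MI orderings", {
  hill <- function(p, stimulus, readout_time) p$Rtot * stimulus / (stimulus + 1e-9)
  levels <- 10^seq(-10.5, -7, length.out = 8)
  mk <- function(cv, noise_sd, fn) {
    spec <- population_spec(levels, n_cells = 60, cv = cv,
                            noise_sd = noise_sd, seed = 8)
    simulate_population(network_params(), spec, response_fn = fn)
  }
  # scenario A vs B: same mean dose-response, CV_A > CV_B -> MI_A < MI_B
  mi_a <- estimate_mi(mk(0.6, 0, hill), n_boot = 0)$mi_bits_bc
  mi_b <- estimate_mi(mk(0.15, 0, hill), n_boot = 0)$mi_bits_bc
  expect_lt(mi_a, mi_b)
  # A -> A': responses and spread scaled together; quantile binning makes the
  # estimate exactly invariant
  hill_scaled <- function(p, stimulus, readout_time) 0.2 * hill(p, stimulus, 0)
  mi_a2 <- estimate_mi(mk(0.6, 0, hill_scaled), n_boot = 0)$mi_bits_bc
  expect_equal(mi_a2, mi_a, tolerance = 1e-9)
  # B -> B': response scaled down, additive spread unchanged -> MI drops
  est_b <- estimate_mi(mk(0, 0.002, hill), n_boot = 100)
  est_b2 <- estimate_mi(mk(0, 0.002, hill_scaled), n_boot = 0)
  expect_lt(est_b2$mi_bits_bc, est_b$ci_lower)
})

test_that("simulate_population drives the network model end to end", {
  spec <- population_spec(c(1e-9, 1e-7), n_cells = 10, cv = 0.3, seed = 2)
  s <- simulate_population(network_params(), spec, readout_time = 60)
  expect_s3_class(s, "cell_samples")
  expect_equal(nrow(s), 20)
  expect_true(all(is.finite(s$response)))
  # the stronger stimulus elicits the larger mean ppERK readout
  means <- tapply(s$response, s$stimulus_index, mean)
  expect_gt(means[[2]], means[[1]])
})
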