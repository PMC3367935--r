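test_that("embedding delay finds the quarter period of a sinusoid", {
  lag <- estimate_delay(sin(2 * pi * (0:999) / 40))
  expect_true(abs(lag - 10) <= 1)
  # invariant to affine shifts of the series
  x <- sin(2 * pi * (0:999) / 64)
  expect_identical(estimate_delay(x), estimate_delay(5 * x - 11))
  expect_error(estimate_delay(rep(1, 500)), "constant")
  expect_error(estimate_delay(sin(1:50)), "200")
})

test_that("a memoryless series yields the minimal delay", {
  for (seed in c(5, 11, 23)) {
    set.seed(seed)
    expect_identical(estimate_delay(stats::rnorm(1200)), 1L)
  }
})

test_that("false nearest neighbours embed a cycle in the plane", {
  x <- sin(2 * pi * (0:799) / 40)
  m <- estimate_dimension(x, lag = 10)
  expect_equal(as.integer(m), 2L)
  expect_warning(estimate_dimension(seq_len(600) * 1.0, lag = 3),
                 "monotone")
  expect_error(estimate_dimension(sin(1:100), lag = 2), "500")
})

test_that("logistic map exponent recovers log 2 across seeds", {
  for (seed in c(1, 2, 3, 4, 5)) {
    x <- generate_fixture("logistic_map", 2000, seed = seed)
    est <- rosenstein_lle(x, embedding_params(1, 2, 1), sample_period = 1)
    expect_lt(abs(est$lambda1 - log(2)) / log(2), 0.1)
    expect_identical(est$classification, "chaotic")
  }
})

test_that("periodic motion has an exponent in the zero band", {
  x <- sin(2 * pi * (0:2999) / 60)
  est <- rosenstein_lle(x, embedding_params(15, 2, 60), sample_period = 1)
  expect_lt(abs(est$lambda1), 0.01)
  expect_identical(est$classification, "limit_cycle_or_quasiperiodic")
})

test_that("exponent estimate is invariant to affine rescaling", {
  x <- generate_fixture("logistic_map", 1500, seed = 9)
  e1 <- rosenstein_lle(x, embedding_params(1, 2, 1), sample_period = 1)
  e2 <- rosenstein_lle(7 * x + 3, embedding_params(1, 2, 1),
                       sample_period = 1)
  expect_equal(e1$lambda1, e2$lambda1, tolerance = 1e-10)
})

test_that("temporal neighbour exclusion prevents spurious convergence", {
  # without the mean-period exclusion, neighbours on the same orbit of a
  # sinusoid converge and drag the slope negative
  x <- sin(2 * pi * (0:2999) / 60)
  excluded <- rosenstein_lle(x, embedding_params(15, 2, 60),
                             sample_period = 1)
  naive <- rosenstein_lle(x, embedding_params(15, 2, 1), sample_period = 1)
  expect_lt(naive$lambda1, excluded$lambda1)
  expect_lt(abs(excluded$lambda1), 0.01)
})

test_that("divergence curve bookkeeping is consistent", {
  x <- generate_fixture("logistic_map", 1200, seed = 2)
  est <- rosenstein_lle(x, embedding_params(1, 2, 1), sample_period = 1)
  expect_length(est$curve$horizon_steps,
                length(est$curve$mean_log_divergence))
  expect_gt(est$curve$n_pairs, 0)
  expect_true(est$r_squared >= 0 && est$r_squared <= 1)
  expect_error(rosenstein_lle(x[1:50]), "short")
})

test_that("exponent sign classifies the attractor", {
  expect_identical(classify_by_lle(0.0995, 0.02), "chaotic")
  expect_identical(classify_by_lle(0.001, 0.02),
                   "limit_cycle_or_quasiperiodic")
  expect_identical(classify_by_lle(-0.5, 0.02), "fixed_point")
  expect_error(classify_by_lle(0.1, 0), "positive")
})

test_that("non-chaotic measure follows the scan and its refinement", {
  scan <- data.frame(alpha = c(0.90, 0.92, 0.94, 0.96, 0.98, 1.0),
                     classification = c(rep("limit_cycle_or_quasiperiodic",
                                            4), "chaotic", "chaotic"))
  p <- nonchaotic_probability(scan)
  expect_equal(as.numeric(p), 0.97) # midpoint of the 0.96/0.98 bracket
  expect_equal(as.numeric(p) + attr(p, "chaotic_measure"), 1)
  # one bisection tightens the bracket
  p2 <- nonchaotic_probability(scan, classify_fun = function(a) TRUE)
  expect_equal(as.numeric(p2), 0.965)
  p3 <- nonchaotic_probability(scan, classify_fun = function(a) FALSE)
  expect_equal(as.numeric(p3), 0.975)
  # widening the chaotic band cannot raise the non-chaotic measure
  scan$lambda1 <- c(-0.001, 0.001, 0.005, 0.015, 0.08, 0.09)
  wide <- nonchaotic_probability(scan, zero_band = 0.05)
  narrow <- nonchaotic_probability(scan, zero_band = 0.01)
  expect_lte(as.numeric(narrow), as.numeric(wide))
  # degenerate scans
  all_per <- data.frame(alpha = c(0.5, 1),
                        classification = rep("limit_cycle_or_quasiperiodic",
                                             2))
  expect_warning(pp <- nonchaotic_probability(all_per), "no chaotic")
  expect_equal(as.numeric(pp), 1)
  all_ch <- data.frame(alpha = c(0.5, 1),
                       classification = rep("chaotic", 2))
  expect_warning(pf <- nonchaotic_probability(all_ch), "grid floor")
  expect_equal(as.numeric(pf), 0.5)
})
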