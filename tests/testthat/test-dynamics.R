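test_that("Goodwin fixed point solves the rate balance exactly", {
  # n = 1, k2 = 1: x (1 + x) = 1, the positive root of x^2 + x - 1
  fp <- goodwin_fixed_point(goodwin_params(n = 1, k2 = 1))
  expect_equal(as.numeric(fp), (sqrt(5) - 1) / 2, tolerance = 1e-12)
  for (n in c(2, 6, 10)) {
    for (k2 in c(0.05, 0.5, 3)) {
      fp <- goodwin_fixed_point(goodwin_params(n = n, k2 = k2))
      expect_lt(abs(attr(fp, "residual")), 1e-12)
    }
  }
  # monotone decreasing in the degradation rate
  roots <- vapply(c(0.05, 0.1, 0.5, 1, 5, 50), function(k2)
    as.numeric(goodwin_fixed_point(goodwin_params(n = 4, k2 = k2))),
    numeric(1))
  expect_true(all(diff(roots) < 0))
  expect_lt(roots[6], 0.05)
})

test_that("three-stage loop stability flips at the secant bound", {
  # stable below the threshold whatever the rate constant
  for (k2 in c(1, 1e-2, 1e-4))
    expect_true(goodwin3_stability(7.9, k2)$stable)
  # above the threshold a suitable rate scaling destabilizes
  expect_false(goodwin3_stability(8.1, 1e-3)$stable)
  # stable <=> all eigenvalue real parts negative (internal consistency)
  rep1 <- goodwin3_stability(9, 1e-3)
  expect_identical(rep1$stable, all(Re(rep1$eigenvalues) < 0))
  # loop gain ratio approaches n u/(1+u) < n; equals 8 at the boundary
  expect_lt(rep1$loop_gain_ratio, 9)
})

test_that("critical Hill coefficient equals the closed-form secant value", {
  nc <- goodwin3_critical_hill()
  secant_value <- 1 / cos(pi / 3)^3 # three identical stages: sec^3(pi/3) = 8
  expect_equal(nc, secant_value, tolerance = 1e-6)
})

test_that("trajectory classification separates the canonical motions", {
  tt <- seq(0, 120, by = 0.05)
  expect_identical(classify_trajectory(rep(2.5, 2000), times = NULL)$label,
                   "fixed_point")
  expect_identical(
    classify_trajectory(exp(-0.1 * tt) * sin(tt), times = tt,
                        transient_fraction = 0.2)$label,
    "damped_oscillation")
  expect_identical(classify_trajectory(sin(tt), times = tt)$label,
                   "sustained_oscillation")
  # erratic peak spacing
  set.seed(42)
  rough <- cumsum(stats::rnorm(3000))
  expect_identical(classify_trajectory(rough, times = NULL)$label,
                   "irregular")
})

test_that("classical delay Goodwin oscillates beyond its Hopf delay", {
  tau_c <- hopf_delay_goodwin(10, 0.1) # about 1.93 time units
  expect_true(tau_c > 1 && tau_c < 3)
  below <- classify_trajectory(goodwin_traj(tau = 1, alpha = 1, t_end = 400))
  above <- classify_trajectory(goodwin_traj(tau = 4, alpha = 1, t_end = 400))
  expect_false(below$label == "sustained_oscillation")
  expect_identical(above$label, "sustained_oscillation")
})

test_that("delay sweep is monotone from stability to oscillation", {
  # runs sized so the post-transient window holds several periods even at
  # the longest delay (the oscillation period scales with tau)
  df <- delay_sweep(goodwin_params(alpha = 1), c(1, 25), t_end = 800)
  expect_equal(nrow(df), 2L)
  expect_false(df$label[1] == "sustained_oscillation")
  expect_identical(df$label[2], "sustained_oscillation")
  # single-delay sweep yields a single row
  one <- delay_sweep(goodwin_params(alpha = 1), 8, t_end = 400)
  expect_equal(nrow(one), 1L)
  # no sustained -> fixed conversion along an increasing delay list
  labels <- delay_sweep(goodwin_params(alpha = 0.9), c(2, 8, 25),
                        t_end = 800)$label
  sustained <- labels == "sustained_oscillation"
  expect_true(all(diff(sustained) >= 0) || !any(sustained))
})

test_that("maxima clustering counts attractor branches", {
  cl <- fracosc:::cluster_maxima(c(1.0001, 1.0002, 3.5, 3.5003), 1e-3)
  expect_length(cl, 2)
  expect_equal(cl, c(1.00015, 3.50015), tolerance = 1e-6)
  expect_length(fracosc:::cluster_maxima(numeric(0), 1e-3), 0)
  expect_length(fracosc:::cluster_maxima(rep(2, 10), 1e-3), 1)
})

test_that("bifurcation scan recovers the branch count of a known signal", {
  # D^1 x = cos(t) + 0.15 cos(t/2): x(t) tracks sin(t) + 0.3 sin(t/2),
  # whose maxima alternate between two distinct heights
  factory <- function(a)
    fde_system(1, function(t, y, ylag, p) cos(t) + 0.15 * cos(t / 2),
               alpha = a)
  bs <- bifurcation_scan(factory, 1.0, observable = 1,
                         transient_fraction = 0.25, t_end = 120, h = 0.01,
                         init = 0, merge_tol = 1e-2)
  expect_equal(bs$n_clusters, 2L)
  # a pure sinusoid gives a single branch
  factory1 <- function(a)
    fde_system(1, function(t, y, ylag, p) cos(t), alpha = a)
  bs1 <- bifurcation_scan(factory1, 1.0, transient_fraction = 0.25,
                          t_end = 120, h = 0.01, init = 0,
                          merge_tol = 1e-2)
  expect_equal(bs1$n_clusters, 1L)
  expect_error(bifurcation_scan(factory, c(0.9, 0.8)), "increasing")
})

test_that("non-negativity is preserved from non-negative histories", {
  for (alpha in c(0.7, 0.9, 1)) {
    for (tau in c(5, 20)) {
      tr <- goodwin_traj(tau = tau, alpha = alpha, t_end = 300)
      expect_identical(tr$status, "ok")
      expect_gt(min(tr$states), -1e-6)
    }
  }
})
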