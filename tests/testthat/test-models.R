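test_that("Hill repression has the right values, bounds and limits", {
  expect_equal(hill_repression(0, 5), 1)
  expect_equal(hill_repression(1, 3), 0.5)
  expect_equal(hill_repression(1, 12), 0.5)
  expect_equal(hill_repression(2, 9), 1 / 513)
  x <- seq(0, 5, by = 0.1)
  y <- hill_repression(x, 4)
  expect_true(all(y > 0 & y <= 1))
  expect_true(all(diff(y) <= 0))
  # large n approaches a step at x = 1
  expect_gt(hill_repression(0.9, 200), 0.999)
  expect_lt(hill_repression(1.1, 200), 0.001)
  expect_error(hill_repression(-0.1, 2), ">= 0")
})

test_that("Goodwin chain rates vanish at the fixed point and cap at 1", {
  p <- goodwin_params(n = 10, k2 = 0.1)
  xs <- goodwin_fixed_point(p)
  expect_equal(goodwin_rhs(xs, p), 0, tolerance = 1e-10)
  expect_equal(goodwin_rhs(0, p), 1) # maximal synthesis, no degradation
  # 3-dim symmetric chain at its fixed point
  fp <- goodwin3_stability(10, 0.5)$fixed_point
  expect_equal(goodwin_rhs(fp, goodwin_params(n = 10, k2 = 0.5)),
               rep(0, 3), tolerance = 1e-9)
  expect_length(goodwin_rhs(c(0.1, 0.2), p), 2)
  expect_error(goodwin_rhs(rep(0.1, 4), p), "dimension")
  expect_error(goodwin_rhs(c(-0.1), p), "non-negative")
})

test_that("model constructors validate their parameters", {
  expect_error(goodwin_params(n = 0.5), "n")
  expect_error(goodwin_params(k2 = 0), "k2")
  expect_error(goodwin_params(tau = -1), "tau")
  expect_error(goodwin_params(alpha = 0), "alpha")
  expect_error(rossler_params(c = -1), "positive")
  p <- rossler_params(preset = "classic")
  expect_equal(c(p$a, p$b, p$c), c(0.2, 0.2, 5.7))
  p <- rossler_params()
  expect_equal(c(p$a, p$b, p$c), c(0.15, 0.20, 10.0))
})

test_that("the fractional delay Goodwin spec delays only the synthesis term", {
  sys <- fractional_delay_goodwin(goodwin_params(tau = 20, alpha = 0.9))
  expect_s3_class(sys, "fde_system")
  expect_equal(sys$dimension, 1L)
  expect_equal(sys$delay, 20)
  expect_equal(sys$alpha, 0.9)
  # degradation acts on the present value: at ylag = x* but y twice x*,
  # the rate must be synthesis(x*) - k2 * (2 x*), not zero
  p <- goodwin_params(tau = 20, alpha = 0.9)
  xs <- as.numeric(goodwin_fixed_point(p))
  r <- fracosc:::rhs_eval_r(sys, 0, 2 * xs, xs)
  expect_equal(r, hill_repression(xs, p$n) - p$k2 * 2 * xs, tolerance = 1e-12)
  # double limit alpha = 1, tau = 0 recovers the classical model
  sys0 <- fractional_delay_goodwin(goodwin_params(tau = 0, alpha = 1))
  expect_equal(sys0$delay, 0)
  expect_equal(sys0$alpha, 1)
  expect_equal(fracosc:::rhs_eval_r(sys0, 0, 0.3, NULL),
               goodwin_rhs(0.3, goodwin_params()))
})

test_that("the classical Goodwin model relaxes to its unique steady state", {
  for (cfg in list(c(n = 6, k2 = 0.3), c(n = 10, k2 = 0.1))) {
    p <- goodwin_params(n = cfg["n"], k2 = cfg["k2"], tau = 0, alpha = 1)
    tr <- solve_fde(fractional_delay_goodwin(p), 0.2, time_grid(20000, 0.01))
    expect_equal(unname(tail(tr$states[, 1], 1)),
                 as.numeric(goodwin_fixed_point(p)), tolerance = 1e-6)
    cl <- classify_trajectory(tr)
    expect_false(cl$label == "sustained_oscillation")
  }
})

test_that("Rossler system is commensurate and vanishes at its equilibria", {
  p <- rossler_params(alpha = 0.95)
  sys <- rossler_system(p)
  expect_equal(sys$dimension, 3L)
  expect_equal(sys$alpha, 0.95) # single shared order
  eq <- rossler_equilibria(p)
  expect_equal(nrow(eq), 2L)
  for (i in 1:2) {
    r <- fracosc:::rhs_eval_r(sys, 0, unname(eq[i, ]), NULL)
    expect_equal(unname(r), rep(0, 3), tolerance = 1e-10)
  }
})

test_that("reinitiation survival is exponential, memoryless, decreasing", {
  expect_equal(reinitiation_survival(2, 0), 1)
  expect_equal(reinitiation_survival(1, log(2)), 0.5)
  t1 <- 0.7; t2 <- 1.9; g <- 0.8
  expect_equal(reinitiation_survival(g, t1 + t2),
               reinitiation_survival(g, t1) * reinitiation_survival(g, t2))
  tt <- seq(0, 5, by = 0.25)
  s <- reinitiation_survival(0.5, tt)
  expect_true(all(diff(s) < 0))
  # log-linear: constant log-slope equal to -gamma
  expect_equal(diff(log(s)) / diff(tt), rep(-0.5, length(tt) - 1))
  expect_error(reinitiation_survival(0, 1), "gamma")
  expect_error(reinitiation_survival(1, -1), "interval")
})

test_that("named presets resolve to solvable systems", {
  for (nm in c("goodwin1", "goodwin3", "goodwin-frac-delay", "rossler",
               "rossler-frac")) {
    mp <- model_preset(nm)
    expect_s3_class(mp$system, "fde_system")
    expect_length(mp$init, mp$system$dimension)
  }
  expect_equal(model_preset("rossler", alpha = 0.93)$params$alpha, 0.93)
  expect_equal(model_preset("goodwin-frac-delay", tau = 12)$params$tau, 12)
  expect_error(model_preset("nope"), "unknown")
})
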