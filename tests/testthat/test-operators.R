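test_that("memory kernel matches the power-law form and its limits", {
  # alpha = 1: constant weight 1 for every elapsed time
  expect_equal(memory_kernel_weight(1, c(0, 0.5, 5, 100)), rep(1, 4))
  # direct evaluation u^(alpha-1)/Gamma(alpha)
  expect_equal(memory_kernel_weight(0.5, 1), 1 / gamma(0.5))
  expect_equal(memory_kernel_weight(0.3, 2), 2^(-0.7) / gamma(0.3))
  # fading memory: strictly decreasing in elapsed time for alpha < 1
  u <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(memory_kernel_weight(0.6, u)) < 0))
  # larger alpha decays more slowly beyond u = 1
  u <- c(2, 5, 20)
  ratio9 <- memory_kernel_weight(0.9, u) / memory_kernel_weight(0.9, 1)
  ratio5 <- memory_kernel_weight(0.5, u) / memory_kernel_weight(0.5, 1)
  expect_true(all(ratio9 > ratio5))
  # singular at zero elapsed time when alpha < 1
  expect_error(memory_kernel_weight(0.5, 0), "singular")
  expect_error(memory_kernel_weight(1.2, 1), "alpha")
})

test_that("kernel mass concentrates near the present as alpha shrinks", {
  # fraction of kernel mass in [t - eps, t] relative to [0, t]; the closed
  # form is (eps/t)^alpha, which tends to 1 (Dirac limit) as alpha -> 0
  t_now <- 5; eps <- 0.1
  frac <- vapply(c(0.8, 0.4, 0.2, 0.05), function(a) {
    tail_mass <- integrate(function(u) memory_kernel_weight(a, u), 0, eps,
                           rel.tol = 1e-10)$value
    total <- integrate(function(u) memory_kernel_weight(a, u), 0, t_now,
                       rel.tol = 1e-10)$value
    tail_mass / total
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
  expect_gt(frac[4], 0.8)
  expect_equal(frac, (eps / t_now)^c(0.8, 0.4, 0.2, 0.05), tolerance = 1e-6)
})

test_that("Riemann-Liouville integral reproduces closed forms", {
  g <- time_grid(200, 0.05)
  tt <- grid_times(g)
  # ordinary integral of 1 at alpha = 1
  I1 <- riemann_liouville_integral(rep(1, 201), 1, g)
  expect_equal(I1$values, tt, tolerance = 1e-12)
  # constant: t^alpha / Gamma(alpha + 1), exact for the product-trapezoid rule
  for (a in c(0.3, 0.5, 0.9)) {
    Ia <- riemann_liouville_integral(rep(1, 201), a, g)
    expect_equal(Ia$values, tt^a / gamma(a + 1), tolerance = 1e-10)
  }
  expect_equal(I1$values[1], 0)
})

test_that("fractional integrals compose: semigroup property", {
  g <- time_grid(400, 0.01)
  tt <- grid_times(g)
  f <- tt
  two_step <- riemann_liouville_integral(
    riemann_liouville_integral(f, 0.4, g), 0.3)
  one_step <- riemann_liouville_integral(f, 0.7, g)
  expect_lt(max(abs(two_step$values - one_step$values)), 1e-4)
  # closed form for f = t: I^0.7 t = t^1.7 / Gamma(2.7)
  expect_equal(one_step$values, tt^1.7 / gamma(2.7), tolerance = 1e-6)
})

test_that("Caputo derivative reproduces closed forms and kills constants", {
  g <- time_grid(200, 0.01)
  tt <- grid_times(g)
  for (a in c(0.4, 0.5, 0.8)) {
    D <- caputo_derivative(rep(3.7, 201), a, g)
    expect_lt(max(abs(D$values)), 1e-10)
    Dt <- caputo_derivative(tt, a, g)
    expect_equal(Dt$values, tt^(1 - a) / gamma(2 - a), tolerance = 1e-8)
  }
  # alpha = 1 reduces to the ordinary first derivative
  D1 <- caputo_derivative(sin(tt), 1, g)
  expect_equal(D1$values[2:200], cos(tt)[2:200], tolerance = 1e-4)
  expect_error(caputo_derivative(c(1, 2), 0.5, time_grid(1, 0.1)), "3 grid")
})

test_that("Caputo inverts the fractional integral, error vanishing with h", {
  errs <- vapply(c(0.02, 0.01, 0.005), function(h) {
    g <- time_grid(round(2 / h), h)
    tt <- grid_times(g)
    f <- sin(tt)
    rec <- caputo_derivative(riemann_liouville_integral(f, 0.6, g), 0.6)
    keep <- tt >= 0.1 # the reconstructed derivative is weakly singular at 0
    max(abs(rec$values[keep] - f[keep]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("both operators are linear in the sampled function", {
  g <- time_grid(150, 0.02)
  tt <- grid_times(g)
  f1 <- sin(tt); f2 <- tt^2
  for (op in list(riemann_liouville_integral, caputo_derivative)) {
    combo <- op(2 * f1 - 3 * f2, 0.6, g)$values
    parts <- 2 * op(f1, 0.6, g)$values - 3 * op(f2, 0.6, g)$values
    expect_equal(combo, parts, tolerance = 1e-10)
  }
})

test_that("Mittag-Leffler evaluation matches known identities", {
  tt <- seq(0, 3, by = 0.25)
  expect_equal(mittag_leffler(1, -tt), exp(-tt), tolerance = 1e-12)
  # E_{1/2}(-x) = exp(x^2) erfc(x)
  skip_if_not_installed("pracma")
  x <- c(0.5, 1, 2)
  expect_equal(mittag_leffler(0.5, -x), exp(x^2) * pracma::erfc(x),
               tolerance = 1e-10)
})
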