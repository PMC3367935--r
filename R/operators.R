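#' Power-law memory kernel of the fractional integral
#'
#' Weight given to a past rate that occurred `elapsed` time units ago when a
#' fractional integral of order `alpha` accumulates it:
#' \deqn{w(u) = u^{\alpha - 1} / \Gamma(\alpha).}
#' For `alpha = 1` the weight is the constant 1 (all past states count
#' equally: each transcriptional event launches de novo). For `alpha < 1`
#' the kernel decays with elapsed time -- "fading memory": recent events
#' dominate, and larger `alpha` decays more slowly. As `alpha` approaches 0
#' the kernel concentrates at zero elapsed time (a Dirac limit, recovering
#' the identity operator).
#'
#' @param alpha derivative/integral order in (0, 1].
#' @param elapsed elapsed time `u >= 0` (vectorized). For `alpha < 1` the
#'   kernel is singular at `u = 0` and an error is signalled there.
#' @return Numeric vector of kernel weights.
#' @examples
#' memory_kernel_weight(1, 5)            # 1: no fading
#' memory_kernel_weight(0.5, 1)          # 1 / gamma(0.5)
#' @export
memory_kernel_weight <- function(alpha, elapsed) {
  alpha <- check_alpha(alpha)
  if (any(!is.finite(elapsed)) || any(elapsed < 0))
    stop("`elapsed` must be finite and >= 0")
  if (alpha < 1 && any(elapsed == 0))
    stop("memory kernel is singular at elapsed = 0 for alpha < 1")
  elapsed^(alpha - 1) / gamma(alpha)
}

# product-trapezoidal weights for the left-sided fractional integral:
# I^a f(t_k) = h^a / Gamma(a+2) * ( a0_k f_0 + sum_{j=1}^{k-1} d_{k-j} f_j + f_k )
# exact for piecewise-linear f.
rl_weights_apply <- function(values, alpha, h) {
  n <- length(values) - 1L
  out <- numeric(n + 1L)
  if (n == 0L) return(out)
  m <- 0:(n + 1L)
  powa1 <- m^(alpha + 1)
  powa <- m^alpha
  dmw <- powa1[3:(n + 2L)] - 2 * powa1[2:(n + 1L)] + powa1[1:n] # d_0..d_{n-1}
  cc <- h^alpha / gamma(alpha + 2)
  for (k in 1:n) {
    a0 <- powa1[k] - (k - 1 - alpha) * powa[k + 1L] # (k-1)^{a+1}-(k-1-a)k^a
    acc <- a0 * values[1L]
    if (k >= 2L)
      acc <- acc + sum(dmw[k - seq_len(k - 1L)] * values[2:k])
    out[k + 1L] <- cc * (acc + values[k + 1L])
  }
  out
}

#' Riemann-Liouville fractional integral
#'
#' Left-sided fractional integral of order `alpha`, the extension of the
#' Cauchy repeated-integral formula to non-integer order:
#' \deqn{I^\alpha f(t) = \frac{1}{\Gamma(\alpha)} \int_0^t (t-s)^{\alpha-1}
#'   f(s)\, ds,}
#' discretized with product-trapezoidal quadrature (exact for piecewise
#' linear integrands). The value at `t = 0` is 0.
#'
#' @param f a [sampled_fn()] or a numeric vector (with `grid` supplied).
#' @param alpha order in (0, 1].
#' @param grid a [time_grid()] when `f` is a plain vector.
#' @return A `sampled_fn` on the same grid.
#' @examples
#' g <- time_grid(100, 0.05)
#' I <- riemann_liouville_integral(rep(1, 101), 0.5, g)
#' # closed form: t^alpha / gamma(alpha + 1)
#' max(abs(I$values - grid_times(g)^0.5 / gamma(1.5)))
#' @export
riemann_liouville_integral <- function(f, alpha, grid = NULL) {
  alpha <- check_alpha(alpha)
  f <- as_sampled(f, grid)
  sampled_fn(f$grid, rl_weights_apply(f$values, alpha, f$grid$h))
}

#' Caputo fractional derivative
#'
#' Left-sided Caputo derivative of order `alpha` in (0, 1]:
#' \deqn{D^\alpha f(t) = \frac{1}{\Gamma(1-\alpha)} \int_0^t
#'   (t-s)^{-\alpha} f'(s)\, ds,}
#' i.e. the Riemann-Liouville integral of order `1 - alpha` applied to the
#' ordinary first derivative. The first derivative is formed by central
#' differences (one-sided at the ends), so at `alpha = 1` the operator
#' reduces to the ordinary derivative. The Caputo derivative of a constant
#' is zero, and `D^alpha` inverts `I^alpha` (the identity property of the
#' operator pair).
#'
#' @inheritParams riemann_liouville_integral
#' @return A `sampled_fn` on the same grid.
#' @examples
#' g <- time_grid(200, 0.01)
#' D <- caputo_derivative(grid_times(g), 0.5, g)   # f(t) = t
#' # closed form: t^{1/2} / gamma(3/2)
#' max(abs(D$values - grid_times(g)^0.5 / gamma(1.5)))
#' @export
caputo_derivative <- function(f, alpha, grid = NULL) {
  alpha <- check_alpha(alpha)
  f <- as_sampled(f, grid)
  v <- f$values
  n <- length(v)
  if (n < 3L) stop("need at least 3 grid points to form a first derivative")
  h <- f$grid$h
  fp <- numeric(n)
  fp[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * h)
  fp[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * h)
  fp[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  if (alpha == 1) return(sampled_fn(f$grid, fp))
  sampled_fn(f$grid, rl_weights_apply(fp, 1 - alpha, h))
}

#' Mittag-Leffler function
#'
#' One-parameter Mittag-Leffler function
#' \eqn{E_\alpha(z) = \sum_{k \ge 0} z^k / \Gamma(\alpha k + 1)},
#' evaluated by direct series summation (adequate for the moderate
#' arguments arising in fractional relaxation, e.g. the solution
#' \eqn{x(t) = E_\alpha(-t^\alpha)} of \eqn{D^\alpha x = -x}).
#'
#' @param alpha order in (0, 1].
#' @param z numeric vector of arguments.
#' @param tol series truncation tolerance.
#' @return Numeric vector `E_alpha(z)`.
#' @examples
#' mittag_leffler(1, -1)      # exp(-1)
#' @export
mittag_leffler <- function(alpha, z, tol = 1e-15) {
  alpha <- check_alpha(alpha)
  vapply(z, function(zi) {
    if (zi == 0) return(1)
    s <- 0
    kmax <- 500L
    for (k in 0:kmax) {
      term <- sign(zi)^k * exp(k * log(abs(zi)) - lgamma(alpha * k + 1))
      s <- s + term
      if (k > 2 && abs(term) < tol * max(abs(s), 1)) break
    }
    s
  }, numeric(1))
}
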