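#' Band-limited Oustaloup approximation of a fractional operator
#'
#' Builds the Oustaloup recursive zero/pole/gain approximation of
#' \eqn{s^\gamma} over the frequency band `[w_low, w_high]`, with a
#' first-order low-pass appended so that the overall rational approximation
#' is strictly proper (the plain recursive filter has equal numerator and
#' denominator degree, which creates algebraic loops when wired into a
#' simulation diagram). Defaults follow standard practice: band
#' `[1e-3, 1e3]` rad per time unit, 5 recursive cells (11 zero/pole pairs),
#' low-pass cutoff at the upper band edge.
#'
#' @param alpha exponent of the approximated operator `s^alpha`; any value
#'   in `(-1, 1)` is accepted (orders `1 - alpha` of the band-limited
#'   differentiator are what the fractional integrator route uses), plus
#'   `alpha = 1` for the pure-differentiator limit.
#' @param w_low,w_high band edges in rad per time unit, `0 < w_low < w_high`.
#' @param n_cells recursion depth N; the filter has `2N + 1` cells.
#' @param lowpass_cutoff cutoff of the appended first-order low-pass.
#' @return Object of class `oustaloup_approx` with fields `zeros`, `poles`,
#'   `gain`, `lowpass_cutoff`, `alpha`, `w_low`, `w_high`, `n_cells`.
#' @examples
#' flt <- oustaloup_filter(0.5)
#' w <- sqrt(flt$w_low * flt$w_high)
#' abs(oustaloup_response(flt, w))   # ~ w^0.5
#' @export
oustaloup_filter <- function(alpha, w_low = 1e-3, w_high = 1e3, n_cells = 5,
                             lowpass_cutoff = w_high) {
  if (!is.numeric(alpha) || length(alpha) != 1L || abs(alpha) > 1)
    stop("`alpha` must be a single number in [-1, 1]")
  if (!is.numeric(w_low) || !is.numeric(w_high) || w_low <= 0 || w_high <= 0)
    stop("band edges must be positive frequencies")
  if (w_low >= w_high) stop("`w_low` must be below `w_high`")
  if (n_cells < 1 || n_cells != round(n_cells)) stop("`n_cells` must be >= 1")
  if (lowpass_cutoff <= 0) stop("`lowpass_cutoff` must be positive")
  N <- as.integer(n_cells)
  k <- seq(-N, N)
  r <- w_high / w_low
  zeros <- -w_low * r^((k + N + 0.5 * (1 - alpha)) / (2 * N + 1))
  poles <- -w_low * r^((k + N + 0.5 * (1 + alpha)) / (2 * N + 1))
  structure(list(alpha = alpha, w_low = w_low, w_high = w_high,
                 n_cells = N, zeros = zeros, poles = poles,
                 gain = w_high^alpha, lowpass_cutoff = lowpass_cutoff),
            class = "oustaloup_approx")
}

#' @rdname oustaloup_filter
#' @param filt an `oustaloup_approx`.
#' @param w numeric vector of frequencies (rad per time unit).
#' @param lowpass include the appended low-pass in the response
#'   (default TRUE).
#' @return `oustaloup_response`: complex frequency response `H(iw)`.
#' @export
oustaloup_response <- function(filt, w, lowpass = TRUE) {
  stopifnot(inherits(filt, "oustaloup_approx"))
  vapply(w, function(wi) {
    s <- 1i * wi
    H <- filt$gain * prod((s - filt$zeros) / (s - filt$poles))
    if (lowpass) H <- H / (1 + s / filt$lowpass_cutoff)
    H
  }, complex(1))
}

#' @export
print.oustaloup_approx <- function(x, ...) {
  cat(sprintf(
    "<oustaloup_approx> s^%g on [%g, %g] rad/time, %d cells (+ low-pass at %g)\n",
    x$alpha, x$w_low, x$w_high, 2 * x$n_cells + 1, x$lowpass_cutoff))
  invisible(x)
}

# First-order-section state-space realization of the filter chain
# u -> gain * prod (s - z_k)/(s - p_k) -> low-pass -> v, used by the
# Oustaloup solver route. Each section (s - z)/(s - p) is realized as
# w' = p w + u, y = (p - z) w + u (poles/zeros stored as negative reals).
oustaloup_sections <- function(filt) {
  list(p = filt$poles, z = filt$zeros, gain = filt$gain,
       wc = filt$lowpass_cutoff, n = length(filt$poles))
}

# advance one evaluation of the chain: given section states W (n_sec x dim)
# and low-pass states v (dim), input u (dim), return list(dW, dv, out = v)
oustaloup_chain_deriv <- function(sec, W, v, u) {
  nsec <- sec$n
  dW <- W
  inp <- u
  for (kk in seq_len(nsec)) {
    dW[kk, ] <- sec$p[kk] * W[kk, ] + inp
    inp <- (sec$p[kk] - sec$z[kk]) * W[kk, ] + inp
  }
  y <- sec$gain * inp
  dv <- sec$wc * (y - v)
  list(dW = dW, dv = dv)
}
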