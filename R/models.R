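#' Goodwin oscillator parameters
#'
#' Parameter bundle for the Goodwin family of negative-feedback
#' transcription models. The normalized one-variable model is
#' \deqn{D^\alpha x(t) = \frac{1}{1 + x(t-\tau)^n} - k_2\, x(t),}
#' with Hill coefficient `n` (the nonlinearity of the repression),
#' degradation rate `k2`, transcriptional delay `tau` (the silent-interval
#' span retarding the inhibitor), and Caputo order `alpha` (the strength of
#' transcriptional memory; `alpha = 1` is ordinary, memoryless-in-kernel
#' dynamics). The synthesis scale is normalized to 1.
#'
#' Defaults (`n = 10`, `k2 = 0.1`) place the model comfortably inside the
#' "sufficient nonlinearity" and "proper timescale balance" regime: `n`
#' above the classical destabilization threshold of 8, and a degradation
#' rate small enough that delay-induced oscillation is reachable.
#'
#' @param n Hill coefficient, `>= 1`.
#' @param k2 degradation rate per unit time, `> 0`.
#' @param tau delay in time units, `>= 0`.
#' @param alpha Caputo order in (0, 1].
#' @return Object of class `goodwin_params`.
#' @examples
#' goodwin_params(n = 10, k2 = 0.1, tau = 20, alpha = 0.9)
#' @export
goodwin_params <- function(n = 10, k2 = 0.1, tau = 0, alpha = 1) {
  if (!is.numeric(n) || n < 1) stop("Hill coefficient `n` must be >= 1")
  if (!is.numeric(k2) || k2 <= 0) stop("degradation rate `k2` must be > 0")
  if (!is.numeric(tau) || tau < 0) stop("delay `tau` must be >= 0")
  alpha <- check_alpha(alpha)
  structure(list(n = as.numeric(n), k2 = as.numeric(k2),
                 tau = as.numeric(tau), alpha = alpha, synthesis_scale = 1),
            class = "goodwin_params")
}

#' Rossler system parameters
#'
#' Parameter bundle for the (fractional) Rossler system. The default
#' preset `"benchmark"` (`a = 0.15`, `b = 0.20`, `c = 10.0`) is the
#' parameter set of the standard largest-Lyapunov-exponent benchmark for
#' this system; `"classic"` (`a = 0.2`, `b = 0.2`, `c = 5.7`) is the other
#' widely used chaotic set.
#'
#' @param a,b,c real parameters (`c > 0`).
#' @param alpha commensurate Caputo order in (0, 1] shared by all three
#'   equations.
#' @param preset `"benchmark"` or `"classic"`; explicit `a`, `b`, `c`
#'   override the preset values.
#' @return Object of class `rossler_params`.
#' @examples
#' rossler_params()                    # benchmark set, alpha = 1
#' rossler_params(preset = "classic")
#' @export
rossler_params <- function(a = NULL, b = NULL, c = NULL, alpha = 1,
                           preset = c("benchmark", "classic")) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 benchmark = list(a = 0.15, b = 0.20, c = 10.0),
                 classic = list(a = 0.2, b = 0.2, c = 5.7))
  if (!is.null(a)) base$a <- a
  if (!is.null(b)) base$b <- b
  if (!is.null(c)) base$c <- c
  if (base$c <= 0) stop("`c` must be positive")
  alpha <- check_alpha(alpha)
  structure(list(a = as.numeric(base$a), b = as.numeric(base$b),
                 c = as.numeric(base$c), alpha = alpha),
            class = "rossler_params")
}

#' Hill repression function
#'
#' Normalized repressive Hill (Michaelis-Menten type) synthesis rate
#' \eqn{1/(1 + x^n)}: full synthesis at zero repressor, half-maximal at
#' `x = 1`, and approaching a step function as `n` grows.
#'
#' @param x repressor concentration, `>= 0` (vectorized).
#' @param n Hill coefficient, `>= 1`.
#' @return Synthesis rate in `(0, 1]`.
#' @examples
#' hill_repression(c(0, 1, 2), n = 9)
#' @export
hill_repression <- function(x, n) {
  if (any(!is.finite(x)) || any(x < 0)) stop("`x` must be finite and >= 0")
  if (n < 1) stop("`n` must be >= 1")
  1 / (1 + x^n)
}

#' Goodwin chain right-hand side
#'
#' Instantaneous rates of the 1-, 2- or 3-variable Goodwin negative
#' feedback loop. The first variable carries the Hill-repressed synthesis
#' term fed back from the last variable; downstream variables form a linear
#' production-degradation chain with symmetric rates (production rate 1
#' from the upstream variable, degradation `k2` for every variable) -- the
#' regime in which the classical Hill-coefficient threshold of 8 holds.
#'
#' @param state concentration vector of length 1, 2 or 3 (non-negative).
#' @param params a [goodwin_params()].
#' @return Rate vector of the same length.
#' @examples
#' p <- goodwin_params(n = 10, k2 = 0.1)
#' goodwin_rhs(c(0.5, 0.5, 0.5), p)
#' @export
goodwin_rhs <- function(state, params) {
  stopifnot(inherits(params, "goodwin_params"))
  d <- length(state)
  if (!d %in% 1:3) stop("Goodwin chain dimension must be 1, 2 or 3")
  if (any(state < 0)) stop("state must be non-negative")
  syn <- hill_repression(state[d], params$n)
  if (d == 1) return(syn - params$k2 * state[1])
  out <- numeric(d)
  out[1] <- syn - params$k2 * state[1]
  for (i in 2:d) out[i] <- state[i - 1] - params$k2 * state[i]
  out
}

#' Fractional delay Goodwin oscillator
#'
#' Builds the one-variable "dual memory" Goodwin system
#' \deqn{D^\alpha x(t) = \frac{1}{1 + x(t-\tau)^n} - k_2\, x(t):}
#' the delayed argument appears only in the synthesis term (the inhibitor
#' produced in one transcriptional event acts on the promoter a silent
#' interval later), while degradation acts on the present value. With
#' `alpha = 1` and `tau = 0` this is exactly the classical one-variable
#' Goodwin model, which does not oscillate sustainably.
#'
#' @param params a [goodwin_params()].
#' @return An [fde_system()] of dimension 1 (compiled right-hand side).
#' @examples
#' fractional_delay_goodwin(goodwin_params(tau = 20, alpha = 0.9))
#' @export
fractional_delay_goodwin <- function(params) {
  stopifnot(inherits(params, "goodwin_params"))
  fde_system(1, "goodwin_delay", alpha = params$alpha, delay = params$tau,
             params = list(n = params$n, k2 = params$k2), labels = "x")
}

#' Commensurate fractional Rossler system
#'
#' Builds the three-variable Rossler system
#' \deqn{D^\alpha x = -y - z,\quad D^\alpha y = x + a y,\quad
#'   D^\alpha z = b + z (x - c),}
#' with the same Caputo order `alpha` in all three equations (commensurate
#' order). At `alpha = 1` and the benchmark parameters the attractor is
#' the classic unimodal folded chaotic one.
#'
#' @param params a [rossler_params()].
#' @return An [fde_system()] of dimension 3 (compiled right-hand side).
#' @examples
#' rossler_system(rossler_params(alpha = 0.95))
#' @export
rossler_system <- function(params) {
  stopifnot(inherits(params, "rossler_params"))
  fde_system(3, "rossler", alpha = params$alpha, delay = 0,
             params = list(a = params$a, b = params$b, c = params$c),
             labels = c("x", "y", "z"))
}

#' Equilibria of the integer-order Rossler system
#'
#' Closed-form fixed points: from \eqn{z = -y} and \eqn{x = -a y}, the
#' remaining equation gives \eqn{a y^2 + c y + b = 0}, so
#' \eqn{x_\pm = (c \pm \sqrt{c^2 - 4ab})/2}, \eqn{y = -x/a}, \eqn{z = x/a};
#' returned as a matrix with one row per equilibrium.
#'
#' @param params a [rossler_params()].
#' @return Matrix with columns `x`, `y`, `z`.
#' @export
rossler_equilibria <- function(params) {
  stopifnot(inherits(params, "rossler_params"))
  a <- params$a; b <- params$b; cc <- params$c
  disc <- cc^2 - 4 * a * b
  if (disc < 0) return(matrix(numeric(0), ncol = 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
  yr <- (-cc + c(1, -1) * sqrt(disc)) / (2 * a)
  cbind(x = -a * yr, y = yr, z = -yr)
}

#' Transcriptional reinitiation survival
#'
#' Probability that a gene still "survives" with reinitiation capability
#' after a silent interval of length `interval`, under a constant decay
#' probability `gamma` per unit time: \eqn{S(\Delta t) = e^{-\gamma \Delta
#' t}}. The complement `1 - S` is the probability of decaying to de novo
#' initiation. As the silent interval vanishes the survival approaches 1
#' and continuous transcription is recovered.
#'
#' @param gamma decay probability per unit time, `> 0`.
#' @param interval silent-interval length `>= 0` (vectorized).
#' @return Survival probabilities in `(0, 1]`.
#' @examples
#' reinitiation_survival(1, log(2))   # 0.5
#' @export
reinitiation_survival <- function(gamma, interval) {
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0")
  if (any(!is.finite(interval)) || any(interval < 0))
    stop("`interval` must be finite and >= 0")
  exp(-gamma * interval)
}

#' Named model presets
#'
#' Resolves a preset name to a ready-to-solve [fde_system()] plus a default
#' history/initial state. Available presets: `goodwin1` (classical
#' one-variable model), `goodwin3` (symmetric three-variable chain),
#' `goodwin-frac-delay` (fractional delay Goodwin oscillator), `rossler`
#' (integer-order benchmark Rossler), `rossler-frac` (commensurate
#' fractional Rossler).
#'
#' @param name preset name.
#' @param alpha,tau,n,k2,a,b,c optional parameter overrides.
#' @return List with elements `system` (an `fde_system`), `init`
#'   (default initial state), and `params` (the parameter bundle).
#' @examples
#' model_preset("rossler-frac", alpha = 0.95)$system
#' @export
model_preset <- function(name, alpha = NULL, tau = NULL, n = NULL, k2 = NULL,
                         a = NULL, b = NULL, c = NULL) {
  pick <- function(x, default) if (is.null(x)) default else x
  switch(name,
    "goodwin1" = {
      p <- goodwin_params(n = pick(n, 10), k2 = pick(k2, 0.1), tau = 0,
                          alpha = pick(alpha, 1))
      list(system = fractional_delay_goodwin(p), init = 0.1, params = p)
    },
    "goodwin3" = {
      p <- goodwin_params(n = pick(n, 10), k2 = pick(k2, 0.1), tau = 0,
                          alpha = pick(alpha, 1))
      sys <- fde_system(3, function(t, y, ylag, pp) goodwin_rhs(pmax(y, 0), pp),
                        alpha = p$alpha, params = p,
                        labels = c("x1", "x2", "x3"))
      list(system = sys, init = rep(0.1, 3), params = p)
    },
    "goodwin-frac-delay" = {
      p <- goodwin_params(n = pick(n, 10), k2 = pick(k2, 0.1),
                          tau = pick(tau, 20), alpha = pick(alpha, 0.9))
      list(system = fractional_delay_goodwin(p), init = 0.1, params = p)
    },
    "rossler" = {
      p <- rossler_params(a = a, b = b, c = c, alpha = pick(alpha, 1))
      list(system = rossler_system(p), init = c(1, 1, 1), params = p)
    },
    "rossler-frac" = {
      p <- rossler_params(a = a, b = b, c = c, alpha = pick(alpha, 0.95))
      list(system = rossler_system(p), init = c(1, 1, 1), params = p)
    },
    stop("unknown model preset: ", name)
  )
}
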