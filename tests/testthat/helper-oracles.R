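# Independent oracles, kept deliberately separate from the package code
# paths they are used to check.

# Mittag-Leffler E_alpha(z) by plain term-by-term summation with gamma();
# adequate for the moderate negative arguments used in the solver tests.
ml_series_ref <- function(alpha, z) {
  vapply(z, function(zi) {
    s <- 0
    term <- 1
    for (k in 0:200) {
      term <- zi^k / gamma(alpha * k + 1)
      s <- s + term
      if (k > 5 && abs(term) < 1e-16) break
    }
    s
  }, numeric(1))
}

# Hopf delay of the classical (alpha = 1) delay Goodwin oscillator from the
# linearization x' = -k2 x - c x(t - tau), c = n x*^(n-1) / (1 + x*^n)^2:
# crossing frequency w = sqrt(c^2 - k2^2), tau_c = acos(-k2/c) / w.
hopf_delay_goodwin <- function(n, k2) {
  xs <- goodwin_fixed_point(goodwin_params(n = n, k2 = k2))
  cg <- n * xs^(n - 1) / (1 + xs^n)^2
  if (cg <= k2) return(Inf) # no crossing: stable for every delay
  w <- sqrt(cg^2 - k2^2)
  acos(-k2 / cg) / w
}

# Method-of-steps closed form for x'(t) = -x(t - 1), constant history 1,
# valid on [0, 2]: x = 1 - t on [0,1]; x = 1 - t + (t-1)^2/2 on [1,2].
method_of_steps_linear <- function(t) {
  ifelse(t <= 1, 1 - t, 1 - t + (t - 1)^2 / 2)
}

# small convenience wrappers
goodwin_traj <- function(n = 10, k2 = 0.1, tau, alpha, t_end = 500,
                         h = 0.01, init = 0.1) {
  p <- goodwin_params(n = n, k2 = k2, tau = tau, alpha = alpha)
  solve_fdde(fractional_delay_goodwin(p), history_spec(init),
             time_grid(round(t_end / h), h))
}

rossler_traj <- function(alpha, t_end = 300, h = 0.01, init = c(1, 1, 1)) {
  solve_fde(rossler_system(rossler_params(alpha = alpha)), init,
            time_grid(round(t_end / h), h))
}

rossler_series <- function(alpha, t_end = 300, transient = 100, h = 0.01,
                           every = 10L) {
  tr <- rossler_traj(alpha, t_end, h)
  keep <- tr$times > transient
  tr$states[keep, 1][seq(1, sum(keep), by = every)]
}
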