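# fracosc — fractional-order dynamics of genetic oscillators

Most deterministic models of genetic oscillation treat transcription as a
continuous process and write ordinary differential equations for it. But
for many genes transcription is temporally discontinuous — bursts
separated by refractory silent intervals. Appending each silent interval
to the transcriptional event that precedes it stretches the running time
of every event, and this "globally slow" timescale turns the ordinary
derivative into a **Caputo fractional derivative** of order
α ∈ (0, 1]:

    D^α x(t) = (1/Γ(1−α)) ∫₀ᵗ (t−s)^(−α) x′(s) ds

The operator weights past rates by the fading kernel
w(u) = u^(α−1)/Γ(α): the system *remembers*, preferentially its recent
past — a deterministic counterpart of transcriptional reinitiation. The
package is for modellers of genetic circuits and synthetic-biology
designers who want to ask what this memory does to oscillation and chaos.
It provides:

* **fractional calculus** — the memory kernel, Riemann–Liouville
  integral, Caputo derivative, and the Mittag-Leffler function
  (`memory_kernel_weight`, `riemann_liouville_integral`,
  `caputo_derivative`, `mittag_leffler`);
* **solvers** — a compiled Adams–Bashforth–Moulton predictor–corrector
  for commensurate fractional (delay) systems, plus a band-limited
  Oustaloup-filter state-space route as an independent cross-check
  (`solve_fde`, `solve_fdde`, `oustaloup_filter`);
* **models** — the fractional delay Goodwin oscillator
  `D^α x = 1/(1 + x(t−τ)ⁿ) − k₂ x` and the commensurate fractional
  Rössler system (`fractional_delay_goodwin`, `rossler_system`,
  `goodwin_rhs`, `hill_repression`, `reinitiation_survival`);
* **dynamics analysis** — steady states, the critical Hill coefficient
  of the three-stage loop, trajectory classification, delay/order
  sweeps, and period-doubling bifurcation scans against the order
  (`goodwin_fixed_point`, `goodwin3_critical_hill`,
  `classify_trajectory`, `delay_sweep`, `order_sweep`,
  `bifurcation_scan`);
* **Lyapunov analysis** — Rosenstein largest-Lyapunov-exponent
  estimation with mutual-information / false-nearest-neighbour embedding
  selection, attractor classification by exponent sign, and the
  non-chaotic probability under a uniform order prior
  (`rosenstein_lle`, `estimate_delay`, `estimate_dimension`,
  `classify_by_lle`, `lle_vs_order`, `nonchaotic_probability`).

The headline dynamical results: oscillation in the one-variable Goodwin
loop needs negative feedback, sufficient nonlinearity, **sufficient
memory** (not merely sufficient delay — lowering α from 0.9 to 0.7 turns
a limit cycle back into a fixed point even at large delay), and balanced
timescales; and fractionizing the Rössler system suppresses its chaos for
all but a thin sliver of orders near 1, so a uniformly drawn order
behaves non-chaotically with probability above 0.98.

## Worked example

Simulate the dual-memory Goodwin oscillator at order 0.9 with delay 20,
classify its long-run motion, and ask two headline numbers:

```r
library(fracosc)

p   <- goodwin_params(n = 10, k2 = 0.1, tau = 20, alpha = 0.9)
sys <- fractional_delay_goodwin(p)
sys
#> <fde_system> dim 1, order alpha = 0.9, delay tau = 20, rhs 'goodwin_delay'

tr <- solve_fdde(sys, history_spec(constant = 0.1), time_grid(80000, 0.01))
classify_trajectory(tr)
#> <trajectory_class> sustained_oscillation (6 peaks, amplitude trend -1.1e-05)

goodwin3_critical_hill()
#> [1] 8

x <- generate_fixture("logistic_map", 2000, seed = 1)
rosenstein_lle(x, embedding_params(1, 2, 1), sample_period = 1)
#> <lle_estimate> lambda1 = 0.6934 /time (chaotic), fit steps [2, 7], r^2 = 1.000
```

The classification says the order-0.9 loop sustains a limit cycle at this
delay (re-running with `alpha = 0.7` yields a damped return to the fixed
point); the critical Hill coefficient 8 is the classical destabilization
threshold of the symmetric three-variable loop; and the logistic-map
exponent 0.6934 recovers the analytic value ln 2 ≈ 0.6931, validating the
divergence estimator.

A shell entry point wraps the same functions
(`inst/scripts/fracosc simulate|sweep|bifurcate|lle|kernel`); every run
echoes its configuration to `config.json` beside its CSV/JSON outputs.

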