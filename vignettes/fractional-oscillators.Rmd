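---
title: "Fractional-order models of genetic oscillation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order models of genetic oscillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model family

Gene transcription is usually written as a continuous dynamical system,
but single-cell imaging shows that for many genes transcription is
temporally discontinuous: bursts of activity separated by refractory
("gene-off") intervals. If each silent interval is appended to the end of
the preceding transcriptional event, the running time of an intact event
stretches, and every state increment happens over a *larger* time
increment than the nominal one. Carried through consistently, this
"globally slow" bookkeeping turns the ordinary time derivative into a
Caputo fractional derivative of order $\alpha \in (0, 1]$:

$$ D^\alpha x(t) \;=\; \frac{1}{\Gamma(1-\alpha)} \int_0^t
   (t-s)^{-\alpha}\, x'(s)\, ds . $$

The operator is non-local: the rate balance at time $t$ is a weighted
average of past rates, with power-law weight
$w(u) = u^{\alpha-1}/\Gamma(\alpha)$ on events $u$ time units in the past
(`memory_kernel_weight()`). At $\alpha = 1$ all weights equal 1 and
ordinary, memoryless dynamics returns — every transcriptional event
launches de novo. For $\alpha < 1$ the kernel fades with elapsed time, so
each event carries information from its predecessors, preferentially the
recent ones — a deterministic counterpart of transcriptional
*reinitiation*, whose likelihood of survival over a silent interval
$\Delta t$ decays as $e^{-\gamma \Delta t}$ (`reinitiation_survival()`).
As $\alpha \to 0$ the kernel concentrates into a Dirac spike at zero
elapsed time. Orders above 1 would weight the remote past *more* than the
present, which has no physiological reading, so the package enforces
$0 < \alpha \le 1$ throughout.

Two classical oscillators carry the analysis:

* the **fractional delay Goodwin oscillator**
  $$ D^\alpha x(t) = \frac{1}{1 + x(t-\tau)^n} - k_2\, x(t), $$
  a "dual memory" system: the Caputo order supplies distributed memory and
  the explicit delay $\tau$ (the silent interval retarding the inhibitor)
  supplies a second, sharp memory;
* the **commensurate fractional Rössler system**
  $D^\alpha x = -y - z$, $D^\alpha y = x + a y$,
  $D^\alpha z = b + z(x - c)$, all three equations sharing the same
  order, as a minimal stand-in for coupled oscillator motifs whose
  integer-order version is chaotic.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| $n$ | Hill coefficient of the repression | 10 | comfortably above the destabilization threshold of 8 for the three-stage loop ("sufficient nonlinearity") |
| $k_2$ | degradation rate (1/time) | 0.1 | small enough that delay-induced oscillation is reachable ("proper timescale balance"); the source analyses fix this constant without printing it, so it is exposed as a configurable default |
| $\tau$ | transcriptional delay (time) | model-specific | swept in the analyses; the classical Hopf delay at $(n, k_2) = (10, 0.1)$ is $\approx 1.93$ |
| $\alpha$ | Caputo order | 1 | the integer-order limit; fractional analyses sweep it |
| $a, b, c$ | Rössler parameters | 0.15, 0.20, 10.0 | the parameter set of the standard largest-Lyapunov-exponent benchmark; the common alternative (0.2, 0.2, 5.7) ships as preset `"classic"` |
| sampling period | spacing of analyzed series | 0.1 time | the convention of the same benchmark; the source does not print its value |
| $h$ | solver step | 0.01 time | resolves delays in $[10, 25]$ and the Rössler spikes with $\ge 10^3$ steps per characteristic period |

## Numerical method

The reference solver (`solve_fde()` / `solve_fdde()`, `method = "abm"`) is
the fractional Adams–Bashforth–Moulton predictor–corrector: a direct
product-integration discretization of the Caputo memory integral, with
weights $b_m = (m+1)^\alpha - m^\alpha$ (predictor, product-rectangle) and
the product-trapezoid corrector weights. The full memory enters every
step, so cost grows quadratically with the number of steps; the inner
convolution is compiled (Rcpp) and the $\alpha = 1$ case telescopes to the
classical Euler/trapezoid pair with $O(1)$ running sums. The same
product-trapezoid weights back the standalone operators
`riemann_liouville_integral()` and `caputo_derivative()`, which makes the
operator identity $D^\alpha I^\alpha f = f$ and the solver consistent by
construction.

The alternative route (`method = "oustaloup"`) reproduces the simulation
practice the model family grew up with: the fractional integrator
$s^{-\alpha}$ is realized as a pure integrator behind a band-limited
Oustaloup recursive filter approximating $s^{1-\alpha}$ (default band
$[10^{-3}, 10^3]$ rad/time, 5 recursion cells, i.e. 11 zero/pole pairs),
with a first-order low-pass appended at the upper band edge so the
rational approximation is strictly proper and no algebraic loop arises.
The augmented state-space system is integrated by `deSolve`. The two
routes agree to $\sim 10^{-2}$ on fractional relaxation problems; the
predictor–corrector is the reference because its error is directly
testable against the Mittag-Leffler closed form and halving $h$ shrinks
it monotonically, while the filter route is kept as an independent
cross-check (and reduces the classical block-diagram scheme at
$\alpha = 1$ up to the low-pass lag, $\sim 10^{-3}$).

Delays are handled through the right-hand side only: the delayed state is
read from the initial history on $[-\tau, 0]$ (constant by default, equal
to the initial value — the step-input convention of block-diagram
simulators) and from linear interpolation of the computed trajectory
afterwards, consistent with the first-order accuracy of the history
treatment. The Caputo integral itself always starts at $t = 0$: the
operator is left-sided, and no fractional weight is placed on the history
segment. A delay below one step is refused rather than rounded. Any state
exceeding $10^8$ in magnitude stops the solver and returns the partial
trajectory flagged `"blowup"` — instability is a reportable outcome, not
a crash.

## Stability and trajectory classification

`goodwin3_critical_hill()` computes the destabilization threshold of the
symmetric three-stage Goodwin loop by bisection on $n$, testing Jacobian
eigenvalues at the fixed point over a grid of rate constants reaching
toward the small-degradation limit. The characteristic equation of three
identical stages is $(\lambda + k_2)^3 = -c$ with loop gain
$c = n u/(1+u) \cdot k_2^3$, $u = x^{*n}$, so instability requires
$n\,u/(1+u) > \sec^3(\pi/3) = 8$; since $u/(1+u) \uparrow 1$ as the rates
shrink, the infimum over rates is exactly 8. The generic eigenvalue route
(rather than the closed form) is kept so the computation extends to
asymmetric rates later; the closed form serves as the cross-check in the
test suite.

`classify_trajectory()` works on the post-transient half of a run
(`transient_fraction = 0.5`): post-transient range below the tolerance
($10^{-3}$ in observable units) is a fixed point; otherwise local maxima
are collected and the least-squares slope of peak height against peak
time is the amplitude trend. *Sustained* oscillation demands at least 5
peaks with trend $\ge -10^{-4}$ per time unit — at the default run
lengths this separates a limit cycle from slow damping; erratic inter-peak
spacing (CV above 0.4) is *irregular*; decaying peaks are *damped*. Run
lengths default to 500 time units for Goodwin sweeps (800 when delays up
to 25 stretch the oscillation period, so the window still holds five
peaks) and 1000 for Rössler scans.

`bifurcation_scan()` collects distinct post-transient local maxima per
order: maxima are parabolically interpolated (removing the $O(h^2)$
grid-sampling jitter) and merged within $10^{-3}$ observable units — wide
enough to absorb numerical jitter, far below the $O(1)$ branch splittings
of a period doubling. One cluster is period-1, two period-2, three
period-3, many a chaotic candidate. On the benchmark Rössler family the
scan resolves the cascade: period-1 up to $\alpha \approx 0.97$, a
doubling near 0.973, period-4 near 0.98, chaos from $\approx 0.982$, and
a period-three window around $\alpha = 0.991$ embedded in the chaotic
region — the classical signature that genuine chaos surrounds it.

## Largest Lyapunov exponent

`rosenstein_lle()` implements the nearest-neighbour divergence method:
delay-embed the scalar series, pair each point with its nearest neighbour
at temporal separation larger than the mean orbital period (reciprocal of
the power-spectrum peak), track mean log-distance over a horizon of up to
six mean periods, and fit a line. Embedding defaults come from the first
significant minimum of the average mutual information (equiprobable bins;
a minimum counts only if it dips 20% below the lag-1 value, which guards
against the binning jitter of noise-free deterministic signals, with the
autocorrelation zero crossing as fallback) and from false nearest
neighbours at the 1% level. Exact recurrences (zero-distance neighbours,
common in noise-free periodic series) are judged by the distance gained
when the embedding is extended, not by the undefined ratio.

The linear-region prescription of the divergence method is qualitative,
and a fixed "fit from zero to half the plateau rise" rule proved biased:
as the series grows and neighbours start closer, that window slides into
the pre-alignment dip and the saturation bend, and the estimate drifts
down with series length. The default here instead fits the *steepest
sustained* segment: among sliding windows one mean period long (at least
5 steps) that end before the curve has completed 80% of its rise, the
window with the largest least-squares slope. Averaging over a whole
period cancels the scalloping of the divergence curve; the 80% guard
keeps the fit off the plateau. The rule was validated jointly on the
fully chaotic logistic map (0.694 vs $\ln 2$), a sinusoid
($|\lambda_1| < 10^{-3}$), and the benchmark Rössler series at lengths
2000–5000 (0.090–0.098, stable, against a published reference value of
0.090 and a source value of +0.0995). An explicit `fit_range` overrides
the rule.

Classification uses a zero band of $\pm 0.02$ inverse time units:
exponents above it are chaotic, below its negative a fixed point,
inside it a limit cycle or quasiperiodic motion. The band separates the
benchmark chaotic value ($\approx +0.1$) from the periodic noise floor at
the default series lengths. `nonchaotic_probability()` treats the
commensurate order as uniform on $(0, 1]$, locates the smallest order
classified chaotic, refines the onset by a single bisection between the
bracketing grid cells (a deliberate desk-scale refinement — one extra
simulation), and reports the measure of the non-chaotic order set. On the
default grid (twelve cells in $(0.9, 1]$ plus anchors at 0.5, 0.7, 0.85)
the onset lands at $\alpha_c \approx 0.981$, consistent with the
bifurcation diagram's cascade, so the non-chaotic probability is just
above 0.98. Cells whose post-transient series is peakless (a relaxing
spiral) are labelled fixed-point directly — the divergence method needs
an extended orbit, and near the Hopf boundary a slowly growing spiral
can otherwise masquerade as divergence; the scan therefore discards a
generous 300-time-unit transient.

## What the fixture generators emulate

`generate_fixture()` provides the oracles the analysis layer is tested
against: the fully chaotic logistic map (known exponent $\ln 2$),
sinusoids and damped sinusoids (known classifications and embedding
parameters), seeded white noise (memoryless series), and a short
deterministic Rössler trajectory. These are noise-free, uniformly sampled,
stationary series; they do not emulate measurement noise, missing samples,
or nonstationary baselines of real transcription recordings, so passing
tests demonstrate correctness of the estimators on clean dynamics, not
robustness to experimental artifacts. All randomness flows from the
single seed in the spec, so identical specs are bit-identical.

## Known limitations

* The quadratic cost of the full-memory predictor–corrector makes runs
  beyond $\sim 10^5$ steps expensive; no short-memory truncation is
  applied because the analyses here stay well below that size.
* Linear stability theory for *delayed fractional* systems (Matignon-type
  sector conditions) is not implemented; classification of the dual
  memory oscillator is simulation-based, matching how the family is
  analyzed in practice.
* The mapping between the reinitiation-survival constant $\gamma$ and the
  order $\alpha$ is qualitative (smaller survival, weaker memory); the
  package exposes them as independent knobs.
* The critical-Hill computation covers the symmetric chain; asymmetric
  rate surfaces are out of scope and signalled as such.
* Embedding defaults target flows sampled near 10 points per orbit; for
  maps, pass an explicit `embedding_params()` (lag 1, dimension 2).

## Problem sizes used by the shipped analyses

The test suite and the acceptance script size their simulations as
follows: operator checks on grids of 100–400 points; solver oracles on
500–2000 steps; Goodwin sweeps 400–800 time units at $h = 0.01$; Rössler
exponent runs 300 time units (100 discarded, 2000 samples analyzed);
order scans 600 time units per cell (300 discarded) over 15 cells plus
one refinement; bifurcation cells 800 time units. These lengths were
chosen so that doubling any of them leaves the reported classifications
unchanged.
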