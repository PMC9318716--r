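---
title: "Estimating the uncertainty of a single-series permutation entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the uncertainty of a single-series permutation entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pevar)
```

## The problem

Permutation entropy (PE) quantifies the irregularity of a scalar time
series through the distribution of its ordinal patterns. Its popularity in
applied work — EEG complexity, seizure onset detection, climatic and
economic records — rests on comparing PE across segments and reading
changes as changes of the source dynamics. Such a comparison is
meaningless without the uncertainty of each PE value, and in observational
settings (geophysics, electrophysiology) one cannot rerun the experiment to
measure that uncertainty the standard way. Analytic routes exist for
memoryless symbol streams, but overlapping windows make the pattern stream
intrinsically non-memoryless, and a faithful Markov treatment would require
estimating up to $m \cdot m!$ transition elements — impractical at useful
$m$. `pevar` implements a phenomenological alternative: measure the PE
spread over an ensemble of surrogate series generated from the single
available record, and scale it.

## The estimator

Windows $\mathbf{x}_n = (x_n, \dots, x_{n+m-1})$ are encoded as the vector
of ranks of their samples, smallest = 1, with ties broken by temporal index
(the earlier sample gets the smaller rank; equality is exact floating-point
equality — no tolerance, since any tolerance would itself be arbitrary).
Note the convention: `encode_window(c(4, 7, 2))` is `(2, 3, 1)` — the rank
*of* each position, not the argsort. The two conventions are element-wise
inverse bijections; entropies are identical, but pattern-level statements
differ. For instance, after an ascending window `(1,2,3)` the overlap
constraint allows exactly three followers, which read
$(1,2,3), (1,3,2), (2,3,1)$ in the rank convention and
$(1,2,3), (1,3,2), (3,1,2)$ in the argsort convention.

With $\hat p_S$ the relative frequency of pattern $S$ over the
$N - m + 1$ windows and $\hat M$ the number of *visited* patterns, the
package reports

$$\hat H_m \;=\; -\sum_{S} \hat p_S \log \hat p_S
  \;+\; \frac{\hat M - 1}{2\,(N - m + 1)},$$

the plug-in estimator plus the Miller–Madow correction for its negative
bias, in nats, together with the normalized value $\hat H_m / \log(m!)$.
Patterns never observed contribute to neither sum; the window count, not
the series length, appears in the correction.

Two closed-form variability baselines are included:

* **memoryless**: $\sigma_{H_m,0} = \sqrt{\hat\Lambda_0 / (N - m + 1)}$,
  where $\hat\Lambda_0 = \sum \hat p_S \log^2 \hat p_S -
  (\sum \hat p_S \log \hat p_S)^2$ is the population variance of
  $-\log p$ — the leading-order standard deviation of a multinomial
  entropy estimate. It vanishes on a uniform distribution, where the
  leading order is degenerate;
* **Harris floor**: $\sqrt{(m! - 1)/2}\,/\,N$, the uniform-multinomial
  standard deviation reached when noise makes all patterns equiprobable.
  (The printed form of this limit in the source literature is
  typographically ambiguous; the package adopts the uniform-multinomial
  variance $(m!-1)/(2N^2)$, which matches the quantity it is meant to
  bound.)

## Surrogate generation

The uncertainty machinery rests on IAAFT (iterative amplitude-adjusted
Fourier transform) surrogates, the standard randomization for continuous
processes when both the amplitude distribution and the autocorrelation
must be preserved — precisely the properties that shape local trajectory
structure and hence the ordinal-pattern statistics. A plain shuffle would
destroy the temporal structure and behave like added white noise; plain
phase randomization loses the amplitude distribution.

Each surrogate starts from a random shuffle and iterates two steps: impose
the original's spectral amplitudes on the current iterate while keeping the
iterate's phases, then rank-remap the inverse transform onto the original's
sorted values. Iteration stops when the squared distance between
consecutive iterates drops below $10^{-6}$ of the squared norm. Two
additional stop rules handle known pathologies: a repeated rank ordering
(IAAFT can enter a fixed point or a 2-cycle, after which no further change
is possible) and an all-constant input, which is its own surrogate. If the
cap `max_iter = 1000` is hit the surrogate is returned flagged
non-converged, with a warning rather than an error, and it is *kept* in the
ensemble so that ensemble size and seeding stay deterministic. By
construction the surrogate's amplitude multiset equals the original's
exactly; the relative spectral discrepancy is of order $N^{-3/2}$.

Because Fourier surrogates implicitly periodize the series, an amplitude
mismatch between the first and last samples leaks power into the spectrum.
Instead of trimming (which discards data — unacceptable for experimental
records), the series is detrended by the straight line through its end
points,
$x_n' = x_n - \frac{x_N - x_1}{N - 1}(n - 1)$,
after which both ends equal $x_1$ (the implementation pins the last value
exactly, not merely to rounding). Within any $m$-window the perturbation is
of order $m\sigma/N$, negligible for $m \ll N$. Detrending is applied to
the original *before* surrogate generation and to every surrogate *after*
it, so ensemble members are end-point matched but their amplitude multisets
differ from the original's by that $O(m\sigma/N)$ perturbation.

### Numerical note: DFT lengths with large prime factors

Base R's `fft` (Singleton mixed-radix) costs $O(Np)$ for a length with a
large prime factor $p$; the package's canonical length
$N = 10006 = 2 \times 5003$ (5003 prime) would make each transform ~40 ms
and an ensemble minutes. For such lengths the package evaluates the DFT via
Bluestein's chirp-z identity — a circular convolution computed with base
`fft` at a padded power-of-2 length — accurate to $\sim 10^{-9}$ relative
and ~20× faster here. Smooth lengths use `fft` directly.

## The uncertainty rule

`estimate_pe_with_uncertainty(x, m, l, alpha, seed)` chains: detrend →
ensemble of `l` surrogates → PE of each → sample standard deviation
$s_{\hat H_m(Y)}$ (denominator $L - 1$) → report the PE *of the detrended
series* (value and uncertainty must refer to the same series) with

$$\Sigma_{\hat H_m} = \alpha \cdot s_{\hat H_m(Y)}.$$

Parameter guidance, with defaults:

| parameter  | default | meaning and rationale |
|------------|---------|-----------------------|
| `m`        | —       | pattern dimension; alphabet is $m!$, so the series must satisfy $N - m + 1 \gg \hat M$. $m = 4\ldots7$ is the practical range at $N \sim 10^4$. |
| `l`        | 100     | ensemble size. $s$ is itself a sample std with relative error $\approx (2L)^{-1/2}$ (7% at 100); larger `l` buys accuracy linearly in cost. |
| `alpha`    | 2       | spread-ratio compensation. Benchmarks below put $s_Y / s_X \in [0.5, 1]$ at moderate noise/correlation, so 2 is conservative; use $\approx 1$ in the noiseless or noise-dominated limits. |
| `max_iter` | 1000    | IAAFT cap; convergence typically takes < 20 iterations at $N \sim 10^4$. |
| `seed`     | `NULL`  | master seed; ensemble member $i$ runs on `seed + i - 1`, making runs bit-reproducible and members independent. |

## The synthetic benches and what they show

Two generators span the situations the method targets:

* **Lorenz with observational noise** — deterministic chaos plus measurement
  noise. $\dot x = a(y-x)$, $\dot y = x(c-z)-y$, $\dot z = xy-bz$ at
  $(10, 8/3, 28)$, integrated with deSolve's Dormand–Prince 7(8) pair at
  tolerance $10^{-10}$ and *sampled* every $dt = 0.3$ (the sampling time; the
  adaptive integrator subdivides internally — the only reading under which
  "integration step = sampling time" is well defined for a high-order
  scheme). The initial state is drawn uniformly from $[-10,10]^3$ (a recorded
  config field, not a hidden constant) and 1000 samples of transient are
  discarded. Gaussian noise of std $\eta \times 7.9252822$ is added to $x$;
  the constant is the pinned long-run std of the noiseless $x$, so the power
  signal-to-noise ratio is exactly $\eta^{-2}$ run to run.
* **ARFIMA** — a purely stochastic long-memory process,
  $x_n = \sum_{k=1}^{100} c_k x_{n-k} + \epsilon_n$ with fractional
  weights $c_k = \rho\,\Gamma(k-\rho)/(\Gamma(1-\rho)\Gamma(k+1))$
  (log-gamma evaluated to avoid overflow), zero pre-history, 1000 burn-in
  samples. $\rho$ tunes the autocorrelation time from white noise
  ($\rho = 0$) towards long memory ($\rho \to 1$); negative $\rho$
  (anti-correlation) is rejected.

The default length 10006 gives exactly $10^4$ windows at $m = 7$ and is
representative of, e.g., 60-s EEG segments.

`reference_pe_std()` plays the role real data cannot: the PE spread across
`l` *independent* realizations (distinct seeds enforced — identical seeds
would fake a zero spread). `ratio_experiment()` then reports
$s_{\hat H_m(Y)} / s_{\hat H_m(X)}$, surrogate spread over reference
spread; this ratio staying within $[0.5, 1]$ at moderate noise/correlation
is the empirical basis of `alpha = 2`. The chaotic regime shows the method's
honest limitation: at very low Lorenz noise ($\eta \lesssim 10^{-2}$)
surrogates — which are consistent with a *linear* stochastic null — carry
higher PE than the deterministic original, and the ratio degrades; the same
does not happen for ARFIMA, whose content is genuinely stochastic at every
correlation time.

What passing these benches does *not* show: performance on nonstationary
records (the method assumes each analyzed segment is stationary),
on point processes (IAAFT is unsuitable there), or at pattern dimensions
where $m! \gtrsim N$, where the Miller–Madow correction itself degrades.

## Validation statistics

For sequences of PE values with uncertainties (e.g. interleaved
eyes-closed/eyes-open EEG segments), `quadratic_drift_fit()` fits a slow
drift $a + bk + ck^2$ (or linear, `degree = 1`) by weighted least squares —
the model is linear in its coefficients, so the weighted normal equations
are solved in closed form (QR), no iteration. If the attached uncertainties
are right and the drift law holds, the minimized normalized residual sum is
$\chi^2_\nu$ with $\nu = n_{points} - n_{coef}$ ($\nu = 3$ for the
canonical six segments and a quadratic); `chi2_3_pdf()` provides
$f_{\chi^2_3}(x) = \sqrt{x/(2\pi)}\,e^{-x/2}$ as the reference density, and
the returned tail probability flags outliers (small values: drift law
broken, or uncertainties underestimated). `z_test_pe()` performs the
two-sided $z$ comparison of two PE values carrying uncertainties; it is
scale-agnostic (nats or normalized, as long as both arguments match — the
EEG-style use is on the normalized scale).

## Numerical and design choices

* Ties in rank encoding use exact floating-point equality; on continuous
  data ties have probability zero, and on quantized data the index rule
  gives a deterministic, documented outcome.
* Pattern bookkeeping encodes each rank vector as an integer in base $m$
  (exact in doubles for $m \le 10$; larger $m$ is rejected, and is anyway
  computationally out of reach for the alphabet).
* The Hermitian structure of the spectrum is preserved automatically: the
  iterate is real, so its DC/Nyquist phases are $\pm 1$ and the
  amplitude-phase recombination stays conjugate-symmetric; the $O(10^{-12})$
  imaginary residue of the inverse transform is dropped.
* Degenerate inputs: constant (and all-zero) series short-circuit as their
  own surrogates, flagged converged with 0 iterations.
* Seeds: every public stochastic entry point takes one integer seed;
  derived streams use the documented `seed + i - 1` rule, and the surrogate
  ensemble inside `ratio_experiment()` starts at `seed + l` so realization
  and surrogate streams cannot collide. Sweeps stride cells by 1000 seeds.
* Lorenz tolerance checks: a chaotic flow amplifies a $10^{-10}$ local
  error by $e^{\lambda t}$ ($\lambda \approx 0.9$), so integrator-tolerance
  convergence is asserted over the initial ~8 Lyapunov times plus
  boundedness over the full trajectory — demanding trajectory-wise
  agreement over hundreds of Lyapunov times would be physically
  meaningless.
* Test problem sizes are scaled to what the statements need: exhaustive
  pattern checks at $m \le 5$ plus the full $7! = 5040$ alphabet; spread
  ratios at the canonical $N = 10006$, $L = 100$ for the headline claim and
  $L = 20\ldots30$ for auxiliary properties; $3 \times 10^5$ samples for
  the Lorenz std calibration; 500 Monte-Carlo draws for the memoryless
  variance oracle and 2000 replicates for the $\chi^2_3$ null calibration.

## Known limitations

* $\alpha$ remains an educated guess inside $[1, 2]$; the package defaults
  to the conservative end rather than estimating $\alpha$ per series.
* At long autocorrelation times (ARFIMA $1 - \rho \lesssim 0.1$) the
  surrogate spread underestimates the reference spread by more than the
  factor 2 that `alpha` compensates; uncertainties there should be read as
  lower bounds.
* Strongly deterministic, nearly noise-free signals inflate surrogate PE
  relative to the original (see above); for such data a surrogate scheme
  preserving determinism would be needed.
* The method presumes stationarity within the analyzed segment — the very
  property PE comparisons are often used to probe; circularity is inherent
  and should be handled at the study-design level.
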