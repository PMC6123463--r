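---
title: "Pure versus conjunctive population codes for multidimensional head direction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pure versus conjunctive population codes for multidimensional head direction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjcode)
```

## The model

A head-direction cell's mean rate is a von-Mises (circular normal)
function of the stimulus.  In 1D,

$$R_i(\varphi) = R\, e^{\kappa(\cos(\varphi - \varphi_i) - 1)} + b,$$

with preferred direction $\varphi_i$, concentration $\kappa$, modulation
depth $R$ (Hz) and baseline $b$ (0 by default: recorded modulation depths
are used as rates).  The *tuning width* is always the full width at half
height above baseline, $\kappa = \ln 2 / (1 - \cos(w/2))$: a 45° width
gives $\kappa = 9.11$, the 90° width fitted to recorded head-direction
cells gives $\kappa = 2.37$.  Conjunctive cells multiply independent
von-Mises factors per dimension.

A *pure* population of $N$ cells splits into $D$ sub-populations of
$N/D$ cells, each tuned to one dimension; a *conjunctive* population has
all $N$ cells tuned to all $D$ dimensions.  Preferred directions are
uniform on $[0, 2\pi)$; spike counts over a decoding window $T$ are
Poisson with mean $R_i \cdot T$.

**Normalization.**  Comparisons are made fair by matching the mean
number of spikes the two populations emit
(`equal_population_rate`): $R_\mathrm{conj} = R_\mathrm{pure}
e^{(D-1)\kappa} / I_0(\kappa)^{D-1}$.  Under that choice the conjunctive
population carries exactly $D$ times the Fisher information of the pure
one, so at large $N$ and $T$ the error ratio
$\epsilon_\mathrm{pure}/\epsilon_\mathrm{conj} \to \sqrt{D}$.  An
`equal_fisher_information` variant (divide by $D$) makes the errors
equal instead, at the cost of the pure population emitting twice the
spikes at $D = 2$.

**Fisher information.**  Closed forms (verified against quadrature to
1e-6 relative in the tests):

$$J_\mathrm{pure} = \tfrac{N}{D} R_\mathrm{pure} T \kappa e^{-\kappa} I_1(\kappa),
\qquad
J_\mathrm{conj} = N R_\mathrm{conj} T \kappa e^{-D\kappa} I_0(\kappa)^{D-1} I_1(\kappa).$$

The FI matrix is proportional to the identity (cross terms vanish by
symmetry), so the per-dimension Cramér–Rao bound is $1/\sqrt{J}$, and
the scalar error convention is the root of the summed squared
per-dimension errors.  The $D$-dimensional conjunctive form follows the
same integral pattern as the 2D case and is checked against the
quadrature oracle rather than a printed formula.  Bessel factors are
evaluated with exponential scaling so nothing overflows at large
$\kappa$.

## Decoding

The ML decoder maximizes the Poisson log-likelihood
$\sum_i n_i \log R_i(s) - T \sum_i R_i(s)$.  For pure populations this
separates into independent 1D problems; conjunctive and mixed
populations are optimized jointly.  We use a dense grid (1° in 1D, 2°
per axis in 2D) followed by Nelder–Mead refinement; grids make brute
force verification exact, and ties break deterministically to the lowest
grid index.  For $D > 2$ the optimizer is multi-started from the
population-vector estimate.  The PV decoder takes, per dimension, the
angle of the count-weighted resultant of preferred directions, and
coincides with ML as $N \to \infty$.

A trial with no spikes (in a sub-population, for per-dimension decoding;
in total, for joint decoding) is *degenerate*: it carries the maximal
error $\pi$ per dimension.  This convention is applied uniformly across
decoders so conditional analyses compare like with like.  Note the
consequence: as $T \to 0$ the mean error tends to the degenerate ceiling
$180\sqrt{2}$ degrees, above the $\approx 138$° ceiling of a decoder
that guesses uniformly.

## Noise models

* **Noise correlations.**  Pairwise correlations decay with
  preferred-direction distance, $c_{ij} = \tfrac14 \cos(2 d_{ij})
  e^{-d_{ij}^2}$ ($d$ in radians: positive for nearby cells, zero at
  45°, weakly negative near 60°), blockwise within each sub-population.
  Counts are drawn through a Gaussian copula (correlated normals →
  Gaussian CDF → inverse Poisson CDF), which preserves Poisson marginals
  exactly; the correlation matrix is repaired to the nearest positive
  semi-definite correlation matrix if needed (eigenvalue floor 1e-10).
  The correlation-aware decoder maximizes a Gaussian likelihood with
  covariance $c_{ij}\sqrt{\mu_i \mu_j} + \text{ridge}$; it is only
  faithful at high counts, and reduces to naive ML exactly when handed
  an identity correlation.
* **Shared gains.**  Per trial, each sub-population's tuning is shifted
  by $\Delta \sim U(-0.2, 0.2)$ (additive; negative Poisson parameters
  clamp to 0) or scaled by a log-normal factor with
  $\mu = -1/2, \sigma^2 = 1$ (multiplicative; mean gain exactly 1).
* **Feed-forward pooling.**  Two upstream rings of $N_0$ evenly spaced
  Poisson cells ($\kappa = 9.1$) feed downstream pure cells (von-Mises
  weighted sums) and conjunctive cells (product of the two pooled
  inputs, divided by $T$ to keep counts linear in $T$).  Neither the
  upstream rate scale nor the absolute downstream scale is pinned down
  by the model; we use a 1 Hz upstream peak rate and calibrate the pooling
  gains by Monte-Carlo so both downstream populations emit the spike
  count of an ideal pure population with a 1 Hz peak.  Downstream
  decoding uses the PV (no closed-form likelihood exists).  Because a
  fixed draw of downstream preferred directions leaves a
  realization-specific bias in the conjunctive PV error, the headline
  pure/conjunctive error ratio is averaged over independent network
  realizations.

## Experiments

`error_surface()` maps the mean scalar error over $(N, T)$;
`regime_map()` compares the pure/conjunctive ratio to $\sqrt D$ with the
contour tolerance $\delta = 0.02$ and reads off $N_{cr}$ — the largest
$N$ at which pure cells still win in absolute terms at $T = 10$ s.
`ratio_2d_1d()` compares the combined 2D error to the per-dimension
error: for Gaussian errors the ratio is $\pi/2$ regardless of scale
(closed forms checked by integration), and heavy-tailed pure-cell errors
at short $T$ push it higher.  `conditional_error()` conditions on each
pure sub-population emitting at least $n_\mathrm{min}$ spikes (the
conjunctive population at least $2 n_\mathrm{min}$, keeping spike
budgets equal); the short-$T$ conjunctive advantage beyond $\sqrt 2$
disappears by $n_\mathrm{min} = 4$, showing it comes from trials where
one pure sub-population goes nearly silent.  `mixed_error()` compares a
mixed population's error to the no-interaction expectation
$\epsilon_p \epsilon_c / \sqrt{\epsilon_p^2 + \epsilon_c^2}$ from adding
inverse squared errors.  `error_vs_fi()` shows the 1D error depends on
$N$ and $T$ only through the Fisher information.

Stimuli are drawn uniformly per repeat; preferred directions are
resampled per repeat by default (exposed as `resample_prefs`), and runs
with the same seed share stimulus sequences across population kinds.

## Behavioral pipeline

Heading angles come from consecutive-sample displacements
($\varphi = \mathrm{angle}(\Delta x + i \Delta y)$,
$\theta = \mathrm{angle}(\sqrt{\Delta x^2 + \Delta y^2} + i \Delta z)$);
zero-displacement samples are masked, not interpolated.  Angular
velocities are wrap-aware absolute first differences times the sampling
rate, combined in quadrature.  Flight splits into navigation vs
maneuvering at the minimum between the two modes of the 20-s horizontal
displacement distribution (after discarding speeds < 0.5 m/s); a
unimodal distribution is an explicit failure, not a silent default.
Crawling splits at a combined angular velocity of 10°/s, boundary
samples inclusive on the fast side.

Tuning curves are occupancy-normalized (6° bins, 0.5 s occupancy floor).
Significance uses circular time-shift shuffles (minimum lag 20 s, 1000
shuffles, 99th percentile — defaults recorded as assumptions, since the
original criteria live in prior work).  The azimuth statistic is the
Rayleigh vector length.  For pitch, whose crawling range is clipped to
about ±45°, we use the occupancy-weighted standard deviation of the
binned rate rather than a peak-to-baseline difference: on synthetic
sessions the peak-to-baseline statistic proved underpowered for
90°-wide tuning confined to a 90° sampled range (it hinges on two noisy
extreme bins), while the dispersion statistic uses the whole curve.
Cells need 120 s of data and 50 spikes per velocity bin; labels are
`conjunctive` when both dimensions are significant, `pure_*` for exactly
one, `untuned` otherwise, with an optional odd/even-second stability
gate ($r > 0.25$) for finer velocity binnings.

## The synthetic world

`generate_trajectory()` is a stand-in for undeposited tracking data, not
a model of animal dynamics.  It switches between a slow
(navigation-like, 3°/s scale) and a fast (maneuvering-like, 30°/s) mode
with mean dwell 20 s — clearly separated by the 10°/s cutoff — and draws
heading increments as absolute values of correlated Gaussians (fast-mode
absolute-velocity correlation 0.26, echoing the reported maneuvering
correlation; the underlying Gaussian correlation is calibrated through
the closed form for $\mathrm{corr}(|Z_1|, |Z_2|)$).  Turn direction is
persistent (sign flips about every 15 s, reversing when the pitch
reflects at ±45°): a sign-i.i.d. random walk would cover the stimulus
circle far too slowly for tuning to be identifiable within a session,
and would leave azimuth–pitch dwell correlations that confound the 1D
curves.  Spikes are drawn by thinning an inhomogeneous Poisson process
along the trajectory, with optional velocity gating (a cell can be pure
at low and conjunctive at high angular velocity).

Cell defaults follow the recorded statistics: 1 Hz peak for pure cells,
3.4 Hz for conjunctive, and $\kappa = 2.37$ (90° width).  We do not use
the 45° width here: a 3.4 Hz conjunctive cell with $\kappa = 9.11$
averages about 0.06 Hz and cannot reach the 50-spike inclusion
criterion in realistic sessions, so label-recovery claims at that width
would be vacuous.

What a green pipeline test establishes: occupancy normalization, shuffle
calibration, inclusion filters and label logic are correct on data with
known structure.  What it does not establish: robustness to tracking
noise, non-Poisson firing, theta rhythmicity, or behavioral sampling
biases beyond the dwell structure generated here.  Detection of
*sustained* conjunctive tuning in the low-velocity bin is intrinsically
hard in this world (slow pitch mixing, clipped range) — mirroring the
empirical observation that conjunctive classifications concentrate at
high angular velocity — so the recovery tests script gated cells rather
than low-velocity conjunctive ones.

## Numerical choices and limitations

* Grid-plus-refinement decoding is exact to the refinement tolerance;
  at very short $T$ flat likelihoods make the (documented) lowest-index
  tie-break visible, which is why acceptance tolerances there are
  stochastic.
* The copula equates the Gaussian and target count correlations; this
  is accurate for the moderate correlations produced by the distance
  rule (≤ 0.25) at the rates used, and is checked empirically.
* The pooling-model error ratio depends on $N$, $N_0$ and the unstated
  rate scales; with the documented choices it averages ≈ 0.76–0.8 over
  network realizations at $N = 2000$, $N_0 = 4000$, $T = 10$ s, with
  substantial spread between realizations.
* Exact 5D ML decoding is infeasible on a dense grid; $D > 2$ uses
  multi-start refinement from the PV, adequate for the ordering claims
  it supports.
* Mean (not median) per-trial scalar errors everywhere, matching the
  expectation convention of the closed forms.
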