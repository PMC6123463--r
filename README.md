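# conjcode

Tools for studying how neural populations encode a multidimensional
circular stimulus — concretely, head direction in azimuth and pitch.
Some head-direction cells are *pure* (tuned to a single angular
dimension), others *conjunctive* (tuned jointly to both).  Which coding
strategy is better?  The answer depends on how many neurons participate
(N) and how much time the decoder has (T): conjunctive cells carry more
Fisher information per spike, but pure cells degrade more gracefully
when neurons or time are scarce.

The package is aimed at computational neuroscientists who want to
reproduce, extend, or stress-test this trade-off, and at
experimentalists who want to run the accompanying behavioral pipeline
(velocity-conditioned tuning classification) on their own trajectory
and spike-time tables.

## What it implements

* **Tuning and information.**  von-Mises tuning curves
  `R exp(kappa (cos(phi - phi_i) - 1))`, width/concentration conversion
  (45° ↔ κ = 9.11, 90° ↔ κ = 2.37), populations with matched
  normalizations, and closed-form Fisher information: per dimension,
  `J_pure = (N/D) R T kappa e^-kappa I1(kappa)` and
  `J_conj = N R T kappa e^-(D kappa) I0(kappa)^(D-1) I1(kappa)`, with
  the Cramér–Rao bound `1/sqrt(J)`.  With spike counts matched, J_conj
  = D · J_pure, so the asymptotic error ratio is `sqrt(D)`.
* **Spiking.**  Independent Poisson counts plus three dependency
  structures: distance-decaying noise correlations via a Gaussian
  copula, shared additive/multiplicative gains, and a two-layer
  feed-forward pooling model.
* **Decoding.**  Maximum-likelihood (grid + refinement, brute-force
  verifiable), population-vector, and a correlation-aware Gaussian
  likelihood decoder; circular errors with the error-π convention for
  spikeless trials.
* **Experiments.**  Error surfaces over (N, T), regime maps at the
  δ = 0.02 contour, the critical size N_cr, 2D/1D error ratios
  (asymptote π/2), spike-conditioned errors, mixed-population synergy,
  and the error-versus-Fisher-information collapse.
* **Behavior + classification.**  Heading/angular-velocity kinematics,
  navigation/maneuvering segmentation, the 10°/s crawl split,
  occupancy-normalized tuning curves, shuffle significance, and
  untuned/pure/conjunctive labels per velocity bin.
* **Synthetic data.**  Two-mode trajectories with correlated
  azimuth/pitch velocities and velocity-gated cells, so the entire
  pipeline is testable offline with known ground truth.

## Worked example

```r
library(conjcode)

fr <- fisher_result(n = 1000, t = 10, kappa = kappa_from_width(45))
fr
#> <fisher_result> N=1000 T=10s kappa=9.11 D=2 (equal_population_rate)
#>   J_pure=5761.87  J_conj=11523.7  (ratio 2)
#>   CR bound: pure 0.7548 deg, conj 0.5337 deg
#>   mean spikes: pure 1341.5, conj 1341.5

ep <- simulate_errors("pure",        1000, 10, 200, seed = 1)$scalar_error
ec <- simulate_errors("conjunctive", 1000, 10, 200, seed = 1)$scalar_error
sprintf("pure %.3f deg, conj %.3f deg, ratio %.3f", mean(ep), mean(ec),
        mean(ep) / mean(ec))
#> [1] "pure 0.952 deg, conj 0.644 deg, ratio 1.478"
```

Reading: with 1000 neurons and 10 s of spikes, both populations emit
~1340 spikes on average, but the conjunctive population carries twice
the Fisher information, so its decoding error is smaller by about
`sqrt(2)` — the simulated ratio 1.478 sits within sampling error of
1.414, i.e. both decoders saturate their Cramér–Rao bounds.  Shrink T to
50 ms and the ratio rises above `sqrt(2) + 0.02` (regime 3); shrink N to
a handful of cells at long T and it drops below 1 (regime 2, pure cells
win outright).

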