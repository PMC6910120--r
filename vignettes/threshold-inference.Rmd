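---
title: "Threshold-based inference for 1-D continua: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based inference for 1-D continua: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(continf)
```

## The problem

Biomechanical waveforms — joint angles, ground reaction forces, plantar
pressures — are usually registered to a common 0–100% cycle and sampled at
Q time nodes (typically 101). Testing a hypothesis at every node multiplies
the number of tests by Q, but adjacent nodes are strongly correlated, so
naive corrections that assume Q independent tests (Bonferroni) are far too
conservative, while ignoring multiplicity (the "uncorrected" 0-D threshold)
inflates the family-wise error rate severely. `continf` implements the two
principled alternatives used in this literature and the machinery to study
when they agree and when they diverge:

* **Random field theory (RFT)** controls the family-wise error rate (FWER)
  of a smooth t continuum using two parameters: the degrees of freedom and
  the residual smoothness (FWHM).
* **Benjamini–Hochberg false discovery rate (FDR)** controls the expected
  proportion of false discoveries among discoveries using only the
  node-wise p-values, and therefore adapts to the signal itself.

## Models and statistics

### The t continuum

For a J×Q sample the package computes node-wise t statistics: one-sample
(`t = mean / (sd/√J)`, ν = J−1), paired (the one-sample t of the
differences), and simple linear regression of node values on a covariate
(slope t, ν = J−2). The unbiased variance estimator (divisor J−1) is used
throughout, matching the Student-t degrees-of-freedom accounting. Nodes
with zero variance or an exact linear fit raise explicit errors instead of
emitting infinite t values, because all downstream threshold logic assumes
a finite field.

### Smoothness: the FWHM

The single smoothness parameter is the full-width-at-half-maximum of the
Gaussian kernel that, convolved with white Gaussian noise, matches the
temporal autocorrelation of the model residuals. `estimate_fwhm()` is the
1-D reduction of the standard gradient-based estimator: residuals are
variance-normalized per node, forward differences are taken over the Q−1
intervals, and the mean squared gradient λ̂ gives `FWHM = √(4 ln 2 / λ̂)`.
One pooled value is returned per dataset (1-D RFT is robust to mildly
non-uniform smoothness, and a single resel count is what the threshold
needs). The estimate is clamped to [0.5, 2Q]: below about half a node the
field is indistinguishable from white noise and the continuum framework
itself stops being meaningful. At J = 10 the estimator carries a small
negative bias (≈ 3–6%), verified by the parameter-recovery tests; this is
the accuracy regime the validation literature reports for small samples.

### The four thresholds

All inference is two-tailed at level α (default 0.05): α/2 per tail,
two-tailed node-wise p-values.

* **Uncorrected**: `qt(1 − α/2, ν)` — the 0-D critical value.
* **Bonferroni**: `qt(1 − α/(2Q), ν)` — valid but conservative under
  smoothness.
* **RFT**: the height u at which the expected Euler characteristic of the
  excursion set of a smooth null t field equals α/2 per tail:
  `P(T > u) + ((Q−1)/FWHM) · (√(4 ln 2)/(2π)) · (1 + u²/ν)^(−(ν−1)/2) = α/2`,
  with `(Q−1)/FWHM` the resel count. The expected EC is used directly as
  the tail probability (the standard high-threshold approximation; at
  α = 0.05 the alternative exponential form differs negligibly, and the
  choice is covered by the simulation-quantile test). The root is bracketed
  and solved to 10⁻⁶.
* **FDR**: p-values are sorted ascending and the largest index i with
  `p(i) ≤ iα/Q` determines the critical p-value `p* = p(i)`; the reported
  threshold is `qt(1 − p*/2, ν)`. When no index satisfies the inequality
  the threshold is *undefined* (no node significant), represented
  explicitly as `NA` — never as an arbitrary large number.

Two conventions exist in the literature for drawing an FDR "threshold
line": the highest satisfying p-value `p(i)` (used here, following the
step-up procedure's accept/reject boundary) and the BH critical line value
`iα/Q`. The rejection *set* is identical; the drawn threshold differs
slightly, and the difference matters only in knife-edge cases such as very
narrow signals where only one or two nodes are significant (see
"Limitations").

## The synthetic world

`generate_noise()` draws white Gaussian noise on a padded domain of length
`Q + 2·ceil(3·FWHM/√(8 ln 2))` and convolves it with a Gaussian kernel of
the requested FWHM, truncating back to Q nodes. Padding (rather than
circular convolution) keeps boundary nodes' covariance identical to
interior nodes' — important because one of the replicated datasets has its
signal at the domain boundary. The kernel is normalized analytically by the
root of its summed squared weights, so every node has exactly unit
population variance and the lag-d autocorrelation is
`exp(−2 ln 2 · d²/FWHM²)`. Requested FWHM below 0.5 nodes is clamped (with
a warning) to 0.5, the white-noise floor.

Signal is a Gaussian pulse `amp · exp(−(x − q)²/(2σ²))`. Because noise has
unit variance, `amp` is the signal-to-noise ratio at the pulse peak. This
identity is preserved across designs by construction:

* *one-sample*: the pulse is added to every observation;
* *paired*: each of the two samples receives noise scaled by 1/√2 so the
  analyzed difference continuum has unit noise variance and the pulse
  appears in it at amplitude `amp`. (With two unit-variance samples the
  difference would have SD √2 and the effective SNR would silently become
  amp/√2.)
* *regression*: observation j receives the pulse scaled by its centered
  covariate value, so `amp` is the slope at the pulse peak per covariate
  unit; the default covariate is the observation index 1..J. An
  alternative — scaling the covariate to unit maximum — was rejected
  because it cannot reproduce the published regression replication: the
  peak systematic effect then never exceeds `amp` noise-SDs and the FDR
  procedure rarely finds any discovery at the replicated parameters.

The tabulated replication parameters (`replicate_table2()`) treat the
pulse center as a 1-based node index: the paired dataset's center "101"
with Q = 101 is the last node, i.e. 100% of stance, which is where the
experimental effect was reported (significance over 95–100% stance). The
0-based reading would place the peak outside the domain; both readings are
defensible, and the 1-based one reproduces the reported behaviour more
faithfully.

What the generator deliberately does **not** emulate: non-Gaussian
marginals, non-stationary (node-varying) smoothness, between-subject
variance heterogeneity, registration error, and vector-valued continua. A
green Monte Carlo test therefore establishes calibration *under the
stationary smooth-Gaussian model*, not robustness to its violations.

## The Monte Carlo harness

`run_no_signal()`, `run_with_signal()` and `estimate_error_rates()` iterate
over factorial grids of (J, FWHM, σ, amp). Defaults mirror the published
experiments: J ∈ 5..50, FWHM ∈ 10..30 (node units at Q = 101, i.e. percent
of the domain), σ ∈ 0..20, amp ∈ 0..4, 10,000 iterations per cell.

Three reproducibility contracts:

* every iteration's seed is derived deterministically from the root seed
  and (J, FWHM, Q, iteration), so identical grids reproduce bit-identically
  and a cell's results do not depend on what other cells are in the grid;
* the seed deliberately excludes the signal parameters, so all signal
  cells at a fixed (J, Q, FWHM) share noise realizations — RFT thresholds,
  which depend only on the noise, are then *identical* across signal
  cells, which is the cleanest way to exhibit "signal moves FDR but not
  RFT";
* seeded generation restores the caller's RNG state.

Aggregation choices that the published experiments leave open:

* **Undefined FDR thresholds** (no BH discovery — the overwhelming
  majority of null iterations) are excluded from the mean FDR threshold
  and their proportion is reported alongside. Under this convention the
  mean no-signal FDR threshold sits slightly below the mean RFT threshold
  across the whole (J, FWHM) grid, reproducing the published no-signal
  surfaces.
* **Empirical FDR** counts a discovery as false when the true pulse
  magnitude at that node is below 1% of `amp` (a Gaussian pulse is nowhere
  exactly zero, so a support cutoff is unavoidable; it is configurable via
  `null_cutoff`). The reported rate is the Benjamini–Hochberg quantity
  E[V/max(R, 1)] — iterations without discoveries contribute zero. The
  conditional-on-discovery mean is reported alongside but is *not* the
  controlled quantity (with a narrow signal it exceeds α even though BH is
  working exactly as designed).

## Numerical choices

* RFT root finding: bracketed `uniroot` to absolute tolerance 10⁻⁶; the
  upper bracket doubles from the uncorrected value until the EC equation
  changes sign, and failure to bracket raises a diagnostic error.
* BH ties: the largest-satisfying-index formulation is tie-safe (equal
  p-values share the decision of their highest rank); the sort is stable.
* Intervals: suprathreshold clusters are maximal runs with `|t|` strictly
  above the threshold, half-open in 0-based node coordinates and closed in
  percent display (`node x → 100·x/(Q−1) %`).
* Degenerate inputs (zero-variance nodes, all-zero residuals, constant
  covariates, perfect fits) raise typed errors early rather than
  propagating NaN/Inf into threshold logic.

## Known limitations

* The EC approximation is a high-threshold approximation; at very rough
  fields (FWHM near the clamp floor) or large α it drifts from the exact
  max-|t| distribution. Within the studied regime (FWHM 10–30, α = 0.05)
  the empirical FWER of the RFT threshold is 0.046–0.047 at J = 10
  (10,000-iteration runs, this package).
* With a very narrow boundary signal only a handful of nodes are BH
  significant, so the FDR threshold `qt(1 − p*/2, ν)` sits on a knife edge
  near the Bonferroni value: the strict ordering
  uncorrected < RFT < FDR < Bonferroni reproduced for the paired
  replication holds in a majority (about two thirds) of seeded replicates,
  not in all of them. The divergence replication (broad weak signal,
  FDR < RFT) is essentially universal across replicates.
* The FWHM estimator assumes stationary smoothness; strongly non-uniform
  smoothness biases the pooled estimate toward the rougher regions.
* Configurations are JSON (not YAML) by design — no YAML parser is part of
  the package's dependency footprint.
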