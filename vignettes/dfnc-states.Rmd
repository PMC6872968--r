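---
title: "Brain-state dynamics from windowed network connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics from windowed network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfncstates)
```

## The problem

Task fMRI is conventionally summarized by static functional connectivity:
one correlation matrix per run. But inter-network coupling reorganizes on
the scale of tens of seconds, and in blocked auditory paradigms
(discrimination, n-back working memory) this reorganization carries
behaviorally relevant information. `dfncstates` implements the standard
dynamic functional network connectivity (dFNC) pipeline for component (or
ROI) time series:

1. nuisance regression (HRF-convolved paradigm, realignment parameters
   and their derivatives), linear detrending and 0.1 Hz low-pass
   filtering;
2. tapered sliding-window Pearson correlation among components;
3. k-means clustering of the pooled windowed connectivity vectors under
   the Manhattan (L1) distance into reoccurring *brain states*, with the
   number of states chosen by an elbow rule on a cluster-validity index;
4. per-run state metrics — transition counts and fractional dwell times —
   compared between tasks by permutation tests and edgewise paired
   t-tests with Benjamini-Hochberg FDR control;
5. brain-behavior association: partial Pearson correlation between state
   metrics and signal-detection sensitivity (d'), controlling mean
   framewise displacement.

A lightweight group ICA (two-stage PCA, repeated-run fixed-point ICA with
a stability index, dual-regression back-reconstruction) is provided for
deriving component time series from voxel data, and a fully seeded
synthetic cohort generator provides ground truth for every stage.

## The windowed-correlation model

Within a window of `w` TRs starting at `t`, connectivity between
components `a` and `b` is the *weighted* Pearson correlation with taper
weights `u` (nonnegative, summing to 1):

\[ r_{ab}(t) = \frac{\sum_i u_i (x_{a,i} - \bar x_a)(x_{b,i} - \bar x_b)}
  {\sqrt{\sum_i u_i (x_{a,i}-\bar x_a)^2}\sqrt{\sum_i u_i (x_{b,i}-\bar x_b)^2}}, \qquad
  \bar x_a = \sum_i u_i\, x_{a,i}. \]

The taper is a rectangle of length `w` convolved with a discrete Gaussian
(sd `sigma` TRs, support ±3 sigma), central `w` samples kept and
renormalized; it suppresses the hard window edges that make plain boxcar
windows ring. Because the weights are nonnegative, every window matrix is
a genuine correlation matrix (symmetric, unit diagonal, PSD up to
roundoff) — a property the test suite asserts.

Defaults: `w = 20` TRs, `sigma = 3` TRs, step 1. With 197 retained
volumes this yields exactly 178 windows per run, the bookkeeping anchor
of the whole design. A 30 s window (`w = 15` at TR = 2 s) is a
configuration away, but it cannot reproduce the 178-window count this
pipeline is anchored to, so 20 TRs is the default.

## State clustering

Pooled windows (all subjects, both tasks; `20 × 2 × 178 = 7120` rows of
91 edges at defaults) are clustered by city-block k-means: assignment by
minimum L1 distance, centroid update by the element-wise median (the L1
Fréchet mean), up to 150 Lloyd iterations, best of 20 k-means++-seeded
restarts by total within-cluster L1 objective. The L1 metric is the
standard choice for high-dimensional, sparsely differing connectivity
vectors. Empty clusters are re-seeded to the farthest point. State labels
are made canonical by descending pooled occupancy, so "state 1" is always
the most visited state and results are reproducible across runs.

The number of states is chosen on a validity curve over `k = 2..10`:
for each k the ratio of mean within-cluster distance to mean pairwise
between-centroid distance. The elbow is operationalized as the interior
k maximizing the discrete second difference
`ratio(k-1) - 2 ratio(k) + ratio(k+1)`, ties toward smaller k; a flat
curve (max second difference < 1e-9) falls back to the smallest k with a
warning. This formulaic rule is a committed choice — the elbow criterion
is often applied by eye, which is not testable.

Per run, `n_transitions` counts adjacent label changes and
`fractional_dwell[s]` is the proportion of windows labeled `s`
(summing to 1 by construction).

## Signal conditioning

- **HRF**: canonical double-gamma, response peak 6 s, undershoot peak
  16 s, peak:undershoot 6:1, unit scale, sampled at TR, normalized to
  unit peak. Its mode sits near 5 s on a dense grid (gamma shape 6,
  scale 1 peaks at 5 s); the "peak 6 s" label refers to the conventional
  parameterization, and the kernel is zero at lag 0.
- **Nuisance model**: HRF-convolved task boxcar, 6 realignment
  parameters, their backward-difference derivatives (first row 0), and an
  intercept; all-zero columns are flagged and dropped, collinear columns
  dropped with a warning. Residualization is ordinary least squares per
  component; it is idempotent and leaves residuals orthogonal to the
  model.
- **Filtering**: linear detrend followed by a zero-phase (forward +
  reverse) 5th-order Butterworth low-pass at 0.1 Hz. The filter is
  designed by bilinear transform in-package; coefficients were checked
  against an independent reference implementation during development, and
  the tests pin the response: ≥ 95% amplitude at 0.05 Hz, ≥ 20 dB
  attenuation at 0.2 Hz (TR = 2 s). Zero-phase filtering uses
  odd-reflection padding with zero initial conditions; edge transients
  are the reason response tests measure away from the series ends.
- **Framewise displacement**: sum of absolute backward differences of the
  3 translations plus 50 mm times the absolute differences of the 3
  rotations; first frame 0. The 50 mm lever arm reproduces the ~0.04 mm
  FD magnitudes the cohort emulates.

## The synthetic cohort: what it states, and what a green test means

The generator's defaults *are* the emulated study design, fixed once:

| parameter | default | why |
|---|---|---|
| subjects × tasks | 20 × 2 | study design |
| run length | 402 s = 201 volumes at TR 2 s | 8 s fixation + 8×(36 s task + 12 s rest) + 10 s closing rest |
| volumes dropped / retained | 4 / 197 | saturation-drop convention; yields 178 windows |
| components / networks | 14 / 7 | retained-component count of the emulated analysis |
| hidden states | 4, Markov switching at TR resolution, stay probability 0.96 | ~4 reoccurring regimes; mean dwell 50 s, comparable to window length yet long enough for distinct segments |
| state covariances | unit-diagonal, compound-symmetric blocks (r = 0.6) over 4 different component coalitions | well-separated correlation-scale states, guaranteed PD |
| task signal | amplitude 1 × HRF-convolved boxcar on components 1-4 | block activation on "auditory" components; removed again by the nuisance step |
| noise | white, sd 0.5 | moderate observation noise on unit-variance components |
| motion | AR(1)-smoothed random walk rescaled to mean FD ~ N(0.04, 0.01) | only FD summaries matter downstream |
| behavior | 96 trials/run (1/3 targets), d' = 2.5 (0-back) / 1.5 (2-back) | blocked-design trial count; easy vs hard task |
| dwell-behavior coupling | 0.58 into the dwell time of state 2 | emulates the reported positive dwell/d' association |

The run-length arithmetic deserves a note: the block list alone sums to
392 s while the emulated run is 402 s; the generator closes the gap with
a final 10 s rest block so that dropping 4 volumes leaves exactly 197 —
the only choice consistent with the 178-window anchor.

**Behavior coupling.** Each run's fractional dwell time in the coupled
state (computed from the true TR-level state sequence) is standardized
within task, mixed with independent Gaussian noise, and injected as a
shift of the subject's *sensitivity*: `d'_i = d'_0 + 0.5 · latent_i`.
A criterion shift would leave d' untouched and could not create the
planted correlation, so the latent acts on sensitivity while the
population mean stays at `d'_0`. Because the estimated d' carries
binomial sampling noise, the mixing weight is inflated analytically
(delta-method sd of the d' estimator at `d'_0`) so that the *realized*
correlation between dwell time and estimated d' targets
`behavior_coupling`. This calibration is closed-form, decided a priori —
not tuned against test outcomes.

**What the generator does not emulate**: volumetric data with spatial
autocorrelation, physiological noise spectra, stimulus category
structure, non-Markovian dwell distributions, or any coupling between
the paradigm and the hidden connectivity regime (an explicit default —
the alternative is a configuration option downstream code can add). A
green planted-recovery test therefore establishes that the estimator
chain recovers the stated statistical structure, not that it would
recover states from arbitrary real data. In particular, at the default
noise level the window estimator's own sampling noise (sd ≈ 0.2 per
edge at w = 20) makes window-level state recovery genuinely hard near
transitions; the recovery *acceptance* test instead plants states in
edge space under the separation premise it verifies (minimum pairwise
centroid L1 distance at least 10× the mean within-state dispersion),
which is the regime the recovery guarantee is stated for. The end-to-end
pipeline reports its honest planted-vs-recovered adjusted Rand index in
every run summary rather than asserting a threshold.

## Inference conventions

- **Permutation test** (transition counts, dwell times): statistic
  `mean(a) − mean(b)`, group labels reshuffled B = 10000 times,
  add-one p-value `(1 + #extreme)/(B + 1)`. Two-sided by default — the
  direction of any between-task difference is not prespecified — with
  one-sided variants by flag. Subjects are treated as two exchangeable
  groups (unpaired), matching the reassignment scheme the test
  emulates; a paired mode is a configuration option.
- **Edgewise state comparison**: a subject's "spatial strength" of state
  s is the mean of its windows assigned to s; paired t per edge across
  subjects, BH-FDR at 0.05 across the 91 edges within each state.
  Subjects lacking windows in the state under either task are excluded
  pairwise; under 3 complete pairs the state is skipped with a warning.
  Zero-difference edges are reported as t = 0 rather than NaN.
- **d'**: `qnorm(hit rate) − qnorm(false-alarm rate)` with the
  log-linear correction (0.5 added to each count, 1 to each
  denominator) applied always, keeping perfect scores finite and the
  estimator antisymmetric under swapping hits with false alarms.
- **Brain-behavior**: first-order partial Pearson correlation
  controlling mean FD, tested by `t = r √(n−3) / √(1−r²)` on `n − 3`
  degrees of freedom.
- A Kolmogorov-Smirnov normality screen is provided as a diagnostic
  (motivating permutation inference) and never gates an analysis.

## Group ICA choices

The decomposition is deliberately "lite": per-subject PCA to `n1 = 27`,
temporal concatenation, group PCA to `n2 = 18` (both counts are inputs,
not estimated — order selection is out of scope), then fixed-point ICA
(logcosh negentropy, symmetric orthogonalization) run 10 times from
random starts. Estimates are pooled across runs and clustered greedily
by absolute correlation, one estimate per run per cluster; each
cluster's centrotype is returned with a stability index
`Iq = mean intra-cluster − mean extra-cluster |r|`, near 1 for reliably
re-found components. Back-reconstruction is dual regression (maps →
time courses → maps), with the sign convention that each map's
peak-magnitude element is positive. The greedy clustering is a stated
approximation to ICASSO's agglomerative procedure; on separable
fixtures both agree, which is the regime the acceptance surface
specifies. Component selection keeps components whose subject-averaged
low-frequency (< 0.1 Hz) power fraction is ≥ 0.5 and whose map peak
avoids an exclusion mask when one is supplied.

## Numerical details worth knowing

- All randomness flows from integer seeds through an internal
  stream-derivation hash (results stay below 2^31); every generator and
  estimator is bit-reproducible for a fixed seed, and `.Random.seed` is
  restored after every seeded call.
- Edge vectorization is row-major over the strict upper triangle;
  `vectorize_fnc()`/`unvectorize_fnc()` are exact inverses and the
  91-edge/14-component arithmetic is asserted in tests.
- Windows with zero weighted variance (constant segments) yield zeroed
  correlations with a warning rather than NaNs.
- k-means ties: assignment keeps the lowest-index nearest centroid; the
  even-size median is the midpoint of the two central order statistics.
- The Lloyd objective is non-increasing across iterations (asserted);
  empty-cluster re-seeding can in principle break monotonicity but is
  only triggered when a centroid loses all members, which the planted
  fixtures never exercise after seeding.

## Known limitations

- The pipeline operates on component/ROI time series; volume-level
  preprocessing (slice timing, realignment, normalization, smoothing)
  is out of scope, as are GLM activation maps, anatomical labeling of
  components, and HMM-style windowless state estimation.
- No Fisher z-transform before clustering by default (an option),
  matching the emulated analysis; covariance regularization of windows
  is not implemented.
- The elbow rule is sensitive to the left end of the validity curve when
  clusters overlap heavily; with genuinely unstructured data it warns
  and returns the smallest k rather than inventing structure.
- CLI configuration is JSON rather than YAML.
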