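# dfncstates

Dynamic functional network connectivity (dFNC) brain-state analysis for
task fMRI component time series — for researchers who want the standard
sliding-window pipeline (nuisance regression, tapered windowed
correlation, L1 k-means brain states, state metrics, permutation and
FDR-corrected inference, motion-adjusted brain-behavior correlation) as
tested, scriptable R, with a fully seeded synthetic multi-subject
generator providing ground truth for every stage.

## The model in brief

Component time series are residualized against an HRF-convolved task
regressor, six realignment parameters and their derivatives, then
detrended and low-pass filtered at 0.1 Hz. Windowed connectivity uses a
tapered window (rectangle of length *w* convolved with a Gaussian,
σ = 3 TRs): within each window the weighted Pearson correlation

r_ab = Σᵢ uᵢ(x_aᵢ − x̄_a)(x_bᵢ − x̄_b) / √(Σᵢ uᵢ(x_aᵢ − x̄_a)²) √(Σᵢ uᵢ(x_bᵢ − x̄_b)²)

is computed for all component pairs (91 edges for 14 components); with
197 retained volumes, *w* = 20 TRs and step 1 this gives 178 windows per
run. Pooled windows are clustered by k-means under the Manhattan
distance (median centroids, max 150 iterations, best of 20 restarts),
with k chosen by an elbow rule (maximum second difference) on the
within/between cluster distance ratio over k = 2..10. Per run, state
*transitions* count adjacent label changes and *fractional dwell time*
is the share of windows per state; tasks are compared by 10 000-fold
permutation tests and edgewise paired t-tests (BH-FDR, 0.05), and state
metrics are related to signal-detection sensitivity d′ =
Φ⁻¹(hit rate) − Φ⁻¹(false-alarm rate) (log-linear corrected) via partial
Pearson correlation controlling mean framewise displacement. A
lightweight group ICA (two-stage PCA 27→18, 10 repeated fixed-point ICA
runs with stability index Iq, dual-regression back-reconstruction) can
derive the component time series from voxel data.

## Worked example

```r
library(dfncstates)
cfg <- run_config(seed = 7, k_range = 2:8, n_replicates = 5, B = 10000,
                  cohort = list(n_subjects = 20))
run_pipeline(cfg, "demo_run")   # ~20 s; writes TSVs, summary.json, report.md
```

`demo_run/report.md` from this exact call:

```
- chosen k: 3
- planted-vs-recovered ARI: 0.393

## Per-task state metrics (means)
- task0back: transitions = 6.7; dwell_1 = 0.524, dwell_2 = 0.256, dwell_3 = 0.219
- task2back: transitions = 8; dwell_1 = 0.468, dwell_2 = 0.279, dwell_3 = 0.254

## Between-task permutation tests
- transitions: diff = -1.3000, p = 0.1748
...
## Brain-behavior partial correlations
- task2back_transitions: r = -0.564, p = 0.0120
- task2back_dwell_state_1: r = 0.523, p = 0.0216
```

Reading this: the generator planted 4 hidden connectivity states, but at
the default observation noise the 20-sample windowed correlations blur
the two most similar regimes, so the elbow merged them (k = 3, ARI
0.39 against the window-level majority truth) — the honest behavior of
the estimator chain at this noise level, reported rather than hidden.
The planted dwell-behavior coupling still surfaces: in the 2-back task
d′ correlates with the dwell time of the most-occupied recovered state
(r = 0.52, p = 0.022) and negatively with transition count
(r = −0.56, p = 0.012). Under the well-separated regime the recovery
guarantee is stated for (centroid separation ≥ 10× within-state
dispersion), clustering and elbow selection are exact — that is what the
acceptance tests verify on 50 replicates. See the methods vignette
(`vignettes/dfnc-states.Rmd`) for the full rationale.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dfnc.R", package="dfncstates"))')" \
    run --out demo_run --seed 7
```

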