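# emgsynergy

Muscle-synergy analysis of locomotor surface EMG, built around a
partitioned nonnegative matrix factorization (NMF) for comparing the motor
modules of patients against a healthy cohort. The package was developed for
studying locomotor pattern generation in spinal muscular atrophy (SMA) —
children whose motoneuron loss reshapes how muscle activity is coordinated —
but every stage is generic to 14-channel locomotor EMG.

## What it does

The EMG envelope matrix $D$ (muscles × time bins) is modelled as
$D \approx WC$ with nonnegative synergies $W$ and activations $C$, fit by
multiplicative-update NMF. On top of that core the package provides:

* **Preprocessing** (`make_envelope`): 50 Hz high-pass FIR → DC removal →
  rectification → 20 Hz low-pass → 20-ms integration → spline de-spiking →
  per-muscle unit-variance normalization.
* **Extraction and dimensionality** (`extract_synergies`,
  `select_dimensionality`): best of 20 random restarts per candidate $N$;
  the dimensionality whose reconstruction
  $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (SST around each muscle's own mean)
  is closest to 80 %.
* **Partitioned fitting** (`fit_basis`, `partition_spec`): a basis split as
  $W = [W^{fixed}_{fit} | W^{up}_{fit} | W^{add}]$ — frozen columns stay
  bit-identical, updated columns start from the originals, added columns
  are extracted fresh.
* **Cross-cohort comparison** (`baseline_r2`, `search_nup_nadd`): fits of
  every control's synergies to every other control build a baseline $R^2$
  distribution; a grid search finds the smallest numbers of updated
  ($N^{up*}$) and additional ($N^{add*}$) synergies that make
  control-to-patient fits statistically non-inferior to that baseline
  (Lilliefors-gated t / Mann–Whitney at the same $N^{up}$, with subset
  enumeration of which synergies to update).
* **Clustering** (`cluster_synergies`, `match_centroids`,
  `flag_normative_overlap`): k-means over l2-normalized synergy vectors
  with silhouette-selected cluster count; scalar-product matching and
  normative-overlap exclusion at SP > 0.8.
* **Characterization** (`segment_span`, `span_distribution`,
  `compare_pre_post`, `residual_profile`, `unevenness_filter`): segment
  span of a synergy (crus/thigh/trunk muscles with normalized components
  > 0.1); per-muscle pre/post-update tests; a motoneuron-loss proxy from
  99th-percentile residual EMG amplitude with the 0.04 unevenness
  exclusion.
* **Clinical statistics** (`pearson_r`, `two_sample`, `multi_group`,
  `fit_sigmoid`): normality-gated tests and the four-parameter sigmoid
  motor-score model $y = a/(1+e^{-b(x-c)})+d$.
* **Synthetic cohorts** (`make_cohort`, `make_sma_cohort`): generated
  control and SMA-like subjects with known ground truth (planted merged
  precursor modules, novel modules, per-muscle attenuation) for end-to-end
  validation.

## Worked example

The packaged clinical table (18 recording sessions from an SMA cohort;
motor function scored on the 0–72 Revised Hammersmith Scale, RHS) ships
with the package:

```r
library(emgsynergy)
rep <- reproduce_table1_stats()
rep
#> Table1Report: 18 rows, 14 with motor scores
#>   left : r = 0.82 (p = 0.00033), sigmoid R2 = 0.963
#>   right: r = 0.82 (p = 0.00033), sigmoid R2 = 0.959
#>   age  : mean 5.94, SD 4.71
rep$sigmoid_left
#> SigmoidFit: y = 58/(1+exp(-7.75(x-1.18))) + 3.74, R2 = 0.9629
```

The Pearson r of 0.82 says motor function correlates strongly with the age
of disease onset; the sigmoid fit localizes the steep gain in preserved
function to onset after about 1.2 years.

A synthetic end-to-end run:

```r
cfg <- sim_config(n_subjects = 3, n_synergies = 4, synth_raw = FALSE, seed = 7)
coh <- make_cohort(cfg)
sel <- select_dimensionality(coh$subjects[[1]]$truth$D,
                             engine_config(n_reps = 5), seed = 1, n_range = 1:8)
sel
#> ExtractionResult: selected n = 4
#>      1      2      3      4      5      6      7      8
#> 0.1506 0.4040 0.6486 0.8457 0.8692 0.8899 0.9066 0.9228
```

The rule selects 4 synergies — the planted truth — because its $R^2$
(0.846) is the closest to the 80 % target. `run_pipeline()` chains
simulate → extract → cluster → baseline → search → characterize → stats on
such a cohort and returns a manifest with per-stage status and timing.

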