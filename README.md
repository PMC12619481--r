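# ebmcascade

Event-based modelling of the temporal cascade of cognitive and gray-matter
decline in type 2 diabetes mellitus (T2DM), with principal-component
reduction of item-level neuropsychological batteries.

Cross-sectional case-control data cannot show *when* each biomarker goes
abnormal — but they can show *in what order*, because markers that turn
abnormal early are abnormal in more subjects. `ebmcascade` implements that
inference end to end for cohorts of T2DM patients and healthy controls
(HC):

* **Preprocessing** — direction harmonization (higher = more abnormal),
  z-scoring against the control group, removal of linear age/sex/education
  effects fitted on controls, optional total-intracranial-volume correction,
  and aggregation of atlas regions into the 35-feature gray-matter-volume
  (GMV) panel (17 bilateral features + cerebellar vermis).
* **PCA reduction** — per-battery correlation-matrix PCA for the CVLT,
  STROOP and WCST with Kaiser–Meyer–Olkin and Bartlett sphericity
  diagnostics, Kaiser (eigenvalue > 1) component selection, and
  eigenvalue-weighted composite scores.
* **Event-based model** — per-biomarker normal/abnormal Gaussian mixtures
  (`P(event | value)` by Bayes), the central event ordering minimising the
  total probabilistic Kendall-tau distance over patients (exhaustive for
  K ≤ 7, local search above), event-centers on a normalized [0, 1]
  timeline, and a stage-coupled generalized EM (`fit_ebm()`) that
  estimates mixtures, sequence and stage prior jointly.
* **Staging** — per-subject posteriors over stages 0..K, EM refinement of
  the stage prior, and the normalized stage in [0, 1] used for group
  comparison.
* **Validation** — bootstrap refits producing a K×K positional-variance
  matrix (rows and columns each sum to 1).
* **Group statistics** — ANCOVA adjusted for age/sex/education, pooled
  two-sample t on the normalized stage, Pearson χ² (no continuity
  correction) for 2×2 tables, partial correlations with clinical chemistry,
  and Benjamini–Hochberg FDR within analysis families.
* **Synthetic cohorts** — a generator with a known ground-truth event
  sequence, binomial stage distributions (patients 0.55, controls 0.45),
  factor-structured battery items and demographic confounds, so the whole
  stack is testable without any subject-level data release.

## Worked example

```r
library(ebmcascade)

co  <- generate_cohort(cohort_spec(K = 6, mu_abnormal = 3, seed = 7))
res <- run_pipeline(co, pipeline_config(bootstrap_B = 25, seed = 7))
res
#> Event-based model pipeline result
#>   biomarkers: 6  subjects: 206
#> Event sequence (earliest first):
#>  position biomarker event_center
#>         1      bm02        0.222
#>         2      bm03        0.394
#>         3      bm05        0.394
#>         4      bm04        0.553
#>         5      bm06        0.664
#>         6      bm01        0.774
#> total probabilistic Kendall distance: 44.89916
#>   stage t-test: t = 3.140, df = 204, p = 0.001938

co$ground_truth$sequence
#> [1] 2 3 5 4 6 1
```

The recovered ordering equals the generator's ground truth: biomarker 2's
event is earliest (event-center 0.22 on the 0–1 timeline), biomarker 1's is
last. The positional-variance matrix from the 25 bootstrap refits puts most
of its mass on that ordering (e.g. `bm02` lands at position 1 in 64% of
refits), quantifying how confident the ordering is. Patients stage higher
than controls — mean normalized stage 0.536 vs 0.431, pooled t = 3.14,
p = 0.0019 — and the covariate-adjusted battery comparisons flag the
planted group deficit in the first principal components (e.g. CVLT-PC1:
F = 23.0, FDR-adjusted p = 8.2e-06).

Lower-level entry points (`preprocess_biomarkers()`, `fit_pca()`,
`fit_abnormality_models()`, `central_ordering()`, `em_refine()`,
`bootstrap_sequence()`, `partial_correlation()`, …) expose each stage
separately; see the package vignette for the model, its assumptions and
its limits.

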