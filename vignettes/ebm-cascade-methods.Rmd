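---
title: "Modelling the temporal cascade of cognitive and gray-matter decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the temporal cascade of cognitive and gray-matter decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmcascade)
```

## The problem

Cross-sectional case-control studies of type 2 diabetes mellitus (T2DM)
measure many cognitive and neuroimaging biomarkers once per subject, yet the
clinically interesting question is longitudinal: *in what order* do these
markers leave their normal range as the disease progresses? The event-based
model (EBM) answers this from purely cross-sectional data by exploiting a
simple fact: a marker that turns abnormal early in the disease is abnormal
in more subjects than one that turns late. `ebmcascade` implements the full
analysis stack around this idea for a cohort of T2DM patients and healthy
controls (HC): item-level neuropsychological batteries are compressed by
principal component analysis (PCA), every biomarker gets a two-component
normal/abnormal mixture, the event sequence and its `[0, 1]` event-centers
are estimated, subjects are staged, ordering uncertainty is bootstrapped,
and the usual covariate-adjusted group statistics are run downstream.

## The model

Each of $K$ biomarkers $j$ has a *normal* density
$f_{n,j} = \mathcal N(\mu_{n,j}, \sigma_{n,j}^2)$ and an *abnormal* density
$f_{a,j} = \mathcal N(\mu_{a,j}, \sigma_{a,j}^2)$ with
$\mu_{a,j} > \mu_{n,j}$ on a harmonized scale (higher = worse). An *event*
is the transition of a biomarker from $f_n$ to $f_a$. The disease is a fixed
permutation $\sigma$ of the $K$ events; a subject at stage
$k \in \{0, \dots, K\}$ has passed the first $k$ events, so their data
likelihood is

$$ L_s(k) = \prod_{m \le k} f_{a,\sigma(m)}(x_{s,\sigma(m)})
           \prod_{m > k} f_{n,\sigma(m)}(x_{s,\sigma(m)}). $$

Given per-biomarker posteriors $p_{sj} = P(\text{event } j \mid x_{sj})$,
the reported *central ordering* is the permutation minimising the total
probabilistic Kendall-tau distance to the patients' posterior profiles,
where a pair ($i$ before $j$) costs $|p_{si} - p_{sj}|$ whenever
$p_{sj} > p_{si}$ — confident discordances cost more, and the distance
reduces to the classic Kendall distance for 0/1 posteriors. *Event-centers*
place each event on a `[0, 1]` timeline as the certainty-weighted mean
normalized rank of that event across subjects, made monotone along the
ordering by pool-adjacent-violators. Staging maximises $\pi_k L_s(k)$ with
the stage prior $\pi$ refined by expectation-maximisation (EM); the group
statistic is the posterior-mean stage divided by $K$.

## Pipeline order and reference population

Biomarkers are processed in a fixed order: direction harmonization (scales
where higher is better, e.g. MoCA, are negated), z-scoring against the HC
rows, and removal of linear age/sex/education effects fitted on the HC rows
only. The HC group is the reference because the EBM's "normal" anchor should
be as disease-free as the design allows; sample standard deviations use the
$n-1$ denominator. Gray-matter volumes can additionally be divided by total
intracranial volume before z-scoring (on by default when a TIV column is
present). Whether covariates should be residualized before the EBM or
absorbed inside it is a genuinely open design point; residualization was
chosen because it keeps every downstream stage covariate-free and matches
the use of a pooled t-test on the resulting stages.

## Battery reduction

The CVLT, STROOP and WCST batteries are reduced per battery: items are
z-scored, PCA is run on the item correlation matrix (so eigenvalues sum to
the item count and eigenvalue thresholds are meaningful), and components
with eigenvalue above 1 are retained (Kaiser rule; the 70%-cumulative /
0.7-eigenvalue rule is also reported and a warning notes disagreements).
Loadings are unit-norm eigenvectors with the largest-magnitude entry made
positive so results do not depend on the eigendecomposition backend; no
rotation is applied. Sampling adequacy is checked with the
Kaiser–Meyer–Olkin statistic and Bartlett's sphericity test before any
reduction is trusted. The per-battery composite averages the selected
component scores weighted by eigenvalue; an equal-weight alternative is
available because the weighting convention is not fixed by the science.

## Mixture estimation and its limits

The central statistical difficulty is estimating each biomarker's mixture.
Two routes are provided:

* `fit_abnormality_models()` fits each column independently by EM from
  several quantile-split starts plus a control-moment start. If the best
  two-component fit does not beat a single Gaussian by the BIC margin for
  its three extra parameters, the column is declared signal-free and
  collapsed to a "mostly normal" configuration (weight 0.05 on a vestigial
  abnormal tail) rather than an arbitrary split of the bulk.
* `fit_ebm()` (used by `run_pipeline()`) couples the columns through the
  stage structure: subjects are ranked by total biomarker burden, each
  mixture is initialized from its best burden changepoint, and a
  generalized EM alternates stage posteriors, mixture re-estimation with
  subject weights $P(\text{stage} \ge \text{position})$, prior updates, and
  a local search over sequences (adjacent swaps and single-element
  insertions) on the total model likelihood, from several sequence starts.

An earlier design that clamped the normal component to the control group's
moments was abandoned: when controls themselves sit at substantial disease
stages — which this cohort's stage summaries imply — their per-biomarker
moments describe a normal/abnormal *mixture*, and the clamp systematically
corrupts every fit.

There is also a hard identifiability limit worth stating precisely. After
per-column standardization, a biomarker whose event has occurred in
essentially *every* subject produces the same single-Gaussian column as one
whose event has occurred in *none*, and the full model likelihood is
invariant to moving such a marker between the two ends of the sequence.
Under the default synthetic conditions below, the earliest event has pooled
prevalence $\approx 0.997$ (less than one expected pre-event subject), so
its position is not estimable by any method; only the generative parameters
themselves distinguish the two ends. With the component overlap that
remains after z-scoring (an effective separation of roughly 1.4 control
standard deviations), mixture weights estimated from $\sim 200$ subjects
are additionally noisy, and recovered orderings should be read through the
bootstrap positional-variance diagram rather than as point estimates.

## The synthetic cohort

Because the study's subject-level data are not deposited, the package ships
a generator whose defaults emulate the study conditions: 119 patients and
87 controls; $K = 10$ biomarkers with a 2-sd normal/abnormal separation;
patient stages $\mathrm{Bin}(K, 0.55)$ and control stages
$\mathrm{Bin}(K, 0.45)$, echoing the published normalized stage means (0.54
vs 0.49) with controls generated from the same event process at earlier
stages; age, education, sex and clinical chemistry drawn per group from the
published demographic table; small linear covariate confounds on every
biomarker (0.02 per year of age, 0.2 for male sex, −0.05 per education
year — plausible magnitudes chosen once, since none are published) which
the preprocessing must remove; and factor-structured battery items (CVLT
18 items / 4 factors, STROOP 11 / 2, WCST 18 / 4, loading 0.8, noise sd
0.6) whose first latent factor is shifted by −0.8 in patients so the
group-comparison layer has signal. The generator does **not** emulate
missing data, scanner or site effects, non-Gaussian score distributions,
floor/ceiling effects, or any coupling between the battery factors and the
biomarker cascade; passing tests therefore certify the estimation
machinery, not robustness to those real-data features.

## Numerical choices

EM tolerance $10^{-6}$ with up to 500 iterations per mixture and a
non-decreasing recorded likelihood trace; standard-deviation floors
prevent degenerate spikes; stage posteriors are computed in log space and
are stable for |z| up to 50; stage-prior EM runs to $10^{-6}$ in the max
norm with up to 1000 iterations and warns (without failing) when the flat
likelihood ridge slows convergence; exhaustive ordering search is used for
$K \le 7$ with lexicographic tie-breaks, local search above; the severity
quantization to $\{0, 1/3, 2/3, 1\}$ rounds ties up and is for reporting
only. Bootstrap resamples that lose an entire group are redrawn at most 10
times. Problem sizes in the tests — 20 replicate cohorts of 206 subjects
for recovery checks, 100 bootstrap resamples, 1000 null replicates for the
FDR calibration — were chosen to keep the whole suite in the
few-minutes range on a single core.

## What the package deliberately omits

No MCMC over sequences, no subtypes, no kernel-density mixtures, no joint
cognitive + imaging model, no varimax rotation, no voxel-level image
handling, no longitudinal trajectories. The anxiety and depression scales
(SAS/SDS) enter the cognitive panel as events by default but can simply be
left out of the biomarker table by the caller.
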