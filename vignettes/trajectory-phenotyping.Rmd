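---
title: "Trajectory phenotyping of sympathetic hyperactivity after TBI"
author: "pshtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory phenotyping of sympathetic hyperactivity after TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshtraj)
```

## The problem

Paroxysmal sympathetic hyperactivity (PSH) — episodic tachycardia,
tachypnea, hypertension, hyperthermia, sweating and posturing — is
common after severe traumatic brain injury (TBI) and is associated with
worse outcomes.  The PSH Assessment Measure quantifies it with two
instruments: the Clinical Feature Scale (CFS), a per-day severity score
in which six categories (heart rate, systolic blood pressure,
respiratory rate, temperature, sweating, posturing) each score 0–3 for
a total of 0–18, and the Diagnosis Likelihood Tool (DLT), a checklist
of 11 binary diagnostic indicators.

A single day's CFS says little about a patient's direction of travel.
`pshtraj` therefore treats the *13-day CFS trajectory* (days 1–13 after
a 24-hour resuscitation window, day 0) as the unit of analysis: it
scores the trajectory from raw vital-sign streams and note flags,
partitions the cohort into trajectory groups by K-means under a dynamic
time warping (DTW) distance, and then asks two clinical questions —
do the groups differ in outcomes, and which admission characteristics
predict group membership?

## Scoring model

Each vital category is scored from **the highest value in each 24-hour
window** anchored at admission (windows are half-open,
`[t0 + d·24h, t0 + (d+1)·24h)`).  Severity thresholds come from the
published instrument and ship as overridable defaults: HR (100, 120,
140) beats/min, SBP (140, 160, 180) mmHg, RR (18, 24, 30) breaths/min,
temperature (37.0, 38.0, 39.0) °C.  Bands are left-closed — a value
equal to a cutpoint takes the higher score.  Sweating and posturing are
scored from pre-extracted daily note flags with the *note rule*: any
mention scores 2 ("moderate"), absence scores 0; daily notes rarely
grade these symptoms finely enough to use the full 0–3 range, so under
this rule an achievable daily maximum is 16 even though the scale's
ceiling is 18.

Missingness is a flagged state, not an error.  A vital category with no
samples in an otherwise documented day scores 0 and is listed in
`missing_categories` (conservative: absence of documentation is treated
as absence of abnormality).  A *wholly* undocumented day is filled at
the trajectory stage — linear interpolation between the nearest scored
neighbours, nearest-value carry at the boundaries — because the
clustering stage needs complete length-13 series; imputed day indices
are reported per patient.  Patients with fewer than two scored days
among days 1–13 are excluded with a logged reason.  These policies are
implementation choices of this package; registries that handled gaps
differently can reproduce their choice by pre-filling the daily table.

"Blood pressure" is interpreted as systolic, as in the instrument;
temperature is Celsius.  The DLT is computed only as a tally of 11
supplied indicator booleans — deriving the indicators from raw data
(episode detection, medication review) is out of scope.

## Trajectory grouping

Similarity between trajectories is DTW with squared local cost, the
symmetric step set {(1,0), (0,1), (1,1)}, both endpoints aligned and no
global band (series are short).  The reported distance is the square
root of the accumulated cost, so the diagonal path recovers the
Euclidean distance and the within-cluster *inertia* is a sum of squared
distances, as in conventional K-means.  DTW is not a metric — triangle
inequality violations are possible and documented rather than guarded
against.  CFS series are deliberately **not** z-normalized: the scale
is absolute and clinically meaningful, and groups differ by level as
well as shape (a `znorm` switch exists).

`kmeans_dtw()` alternates nearest-centroid assignment (ties to the
lowest centroid index) with centroid refits by DTW barycenter averaging
(DBA), initialized at the within-cluster medoid; the refit is kept only
if it does not worsen the within-cluster cost, which guarantees a
monotone inertia trace.  Ten random restarts (distinct sub-seeds
derived from one seed) are run by default and the best inertia wins;
an emptied cluster is reseeded with the row farthest from its centroid.
Fitted groups are renumbered by ascending mean of the centroid's first
three days, so "Group 1 = lowest early CFS" is stable across seeds.

The number of groups is suggested by the elbow of the inertia curve —
the interior `k` maximizing the discrete second difference, ties to the
smallest `k`.  This automatic rule finds the *sharpest* kink, which on
curves with one dominant early drop sits at the smallest plausible `k`;
it is a screening heuristic, not a verdict.  The curve itself is always
returned so that the final choice can incorporate clinical judgment, and
on the default synthetic cohort (below) the rule illustrates exactly why
that matters: it proposes `k = 3` (merging the increasing and decreasing
shapes, which are the two closest archetypes under DTW) while the
four-group model is the one that separates all generating shapes with
adjusted Rand index 1.0.  A silhouette diagnostic on the DTW distance
matrix is provided as a second opinion.

## Outcome association and prediction

Trajectory groups are related to outcomes with the field's standard
toolkit: Pearson chi-squared tests (no continuity correction) for
categorical outcomes and one-way ANOVA for continuous ones, raw
p-values at a 0.05 threshold with no multiple-testing correction —
matching how such cohort tables are conventionally reported.  ANOVA is
used for all continuous outcomes, including skewed stay durations, for
fidelity to that convention; a rank-based alternative can be swapped in
by the user where robustness matters more than comparability.
Per-group PSH odds use Wald intervals on the log-odds scale (a zero
cell yields a flagged, undefined interval rather than a corrected one);
per-group DLT means use t intervals.

Admission predictors are screened univariately (ANOVA / chi-squared at
alpha 0.05) and the survivors enter a forward-stepwise **multinomial
logistic regression** on group membership, reference Group 1.  The fit
is by Newton–Raphson on the softmax log-likelihood with the reference
group's coefficients fixed at zero; because the link is canonical the
observed and expected information coincide, and coefficient covariance
is the inverse information at the optimum.  Convergence requires a
maximal score component below 1e-8 or a relative log-likelihood change
below 1e-10; step halving plus a trust-region cap guard the ascent, and
coefficients exceeding |beta| = 30 are flagged as probable separation
(the fit is returned, marked non-converged).  The stepwise entry
criterion is the likelihood-ratio test (chosen over Wald for stability
at moderate n; the historical choice in such analyses is rarely
reported).  Multi-level categorical features are dummy-coded against
their most frequent level and enter or leave as a block.  Continuous
covariates are not standardized, so odds ratios are per natural unit
(per year of age, per motor-GCS point).  Missing covariate values are
handled complete-case per fitted model, with dropped counts logged.

## The synthetic cohort

Real vital-sign streams from such registries are not redistributable,
so the package ships a generator that emulates the *structure* the
analysis assumes, with ground truth for every stage.  Four trajectory
archetypes (persistently low ≈ 2; decreasing 8 → 3; increasing 3 → 9;
persistently high ≈ 10 CFS points, linear over days 1–13) are sampled
with prevalences 14/33/29/24%.  Daily totals are the archetype value
plus Gaussian noise (SD 1.5), rounded and clipped; each total is split
across the six categories by a deterministic greedy rule (symptom
points first for totals above 12, then vitals round-robin), and raw
vitals are drawn *inside* the band that reproduces each target
sub-score, so scoring the generated data recovers the generated truth
exactly — a round-trip identity the tests exercise on a thousand random
patient-days.

Covariates and outcomes are generated group-first (labels drawn, then
conditioned): age is truncated-normal with group means 52/48/40/38
years (SD 18, range 18–95) — note that truncation raises the realized
group means slightly above the nominal ones; motor GCS is a discretized
group-shifted normal centred at 4/5/3/2; PSH diagnosis is Bernoulli
with group probabilities 0.26/0.38/0.57/0.65; the DLT is Binomial(11,
q) with q rising across groups; ICU stay and ventilation days are
group-shifted log-normals; discharge GCS and survival are independent
of group.  These constants mirror the group-level descriptive tables of
an acute-TBI cohort and are generator parameters, not reproduction
claims.

What the generator does **not** emulate: intra-day dynamics (circadian
rhythm, discrete paroxysms), informative missingness, covariate
correlation structure beyond the group effect, or measurement error in
note flags.  Passing tests on this cohort therefore demonstrate that
the pipeline recovers structure *of the kind assumed*, not that it
would behave identically on any particular registry.

## Numerical choices and problem sizes

Default test and example sizes are chosen so the whole suite runs
comfortably on a laptop: cluster-recovery checks use N = 200 patients
with 10 restarts; permutation cross-checks use 1e5 fixed-margin tables;
null-size checks use 1000 replicates at N = 200; parameter-recovery
checks use n = 5000 over 20 seeds; stepwise-recovery checks use 50
replicates at the cohort's size, N = 221.  Two behaviours of that last
simulation are worth knowing: with Table-scale effect sizes the
univariate ANOVA power for the age effect is about 0.93 at N = 221, and
forward selection at alpha 0.05 with five pure-noise candidates admits
some noise feature in roughly one run in ten — so exact recovery of the
true feature set lands near 75%, a property of the procedure at this
sample size rather than a defect of the implementation.

## Limitations

Free-text note NLP, PSH case adjudication from medication records,
episode-level paroxysm detection, model-based trajectory mixtures
(polynomial latent-class growth models), soft clustering and penalized
or cross-validated regression are all out of scope.  The elbow rule is
a heuristic with a documented failure mode; treat `select_k_elbow()` as
a proposal to be reviewed alongside the curve and the silhouette.
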