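# pshtraj

Trajectory phenotyping of sympathetic hyperactivity after traumatic
brain injury (TBI), for neurocritical-care researchers working with
electronic-health-record vital signs.

Paroxysmal sympathetic hyperactivity (PSH) — episodic tachycardia,
tachypnea, hypertension, hyperthermia, sweating and posturing — affects
a large fraction of critically ill TBI patients.  Its daily severity is
quantified by the Clinical Feature Scale (CFS) of the PSH Assessment
Measure: six categories (HR, SBP, RR, temperature, sweating, posturing)
each scored 0–3, total 0–18, with vital categories scored from the
highest value in each 24-hour window after admission and the symptom
categories from daily clinical-note mentions (any mention = 2, absence
= 0).  `pshtraj` implements an end-to-end, group-based trajectory
modelling pipeline over these scores:

1. **Scoring** — `window_vitals()`, `daily_cfs()`, `score_cohort()`,
   `build_trajectory()`: raw vital streams + note flags → daily CFS →
   13-day trajectories (days 1–13; day 0 is the resuscitation window
   and is dropped); `dlt_tally()` for the 11-indicator Diagnosis
   Likelihood Tool.
2. **Clustering** — `kmeans_dtw()`: K-means under a dynamic time
   warping (DTW) distance with squared local cost
   (`dtw_distance(x, y) = sqrt(min over warping paths of the summed
   squared differences)`), centroids refit by DTW barycenter averaging;
   `inertia_curve()` + `select_k_elbow()` for choosing the group count,
   `silhouette_dtw()` as a diagnostic.
3. **Outcomes** — `outcome_summary()`, `chi_square_test()`,
   `one_way_anova()`, `group_odds()`, `group_mean_ci()`: group-wise
   association tables in the conventional cohort-study style.
4. **Predictors** — `univariate_screen()` + `forward_stepwise()` over a
   Newton–Raphson multinomial logistic regression
   (`fit_multinomial_logit()`, softmax link, reference group fixed at
   zero), with `odds_ratios()` per non-reference group.
5. **Synthetic cohorts** — `generate_cohort()`: four latent trajectory
   archetypes (persistently low / decreasing / increasing / persistently
   high), covariates and outcomes conditioned on the latent group, and
   raw vitals generated to *exactly* reproduce the intended daily
   scores, so every stage of the pipeline is testable with no patient
   data.

## Worked example

```r
library(pshtraj)

cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 42))
daily  <- score_cohort(cohort$vitals, cohort$flags, cohort$admissions)
traj   <- trajectory_matrix(daily)
fit    <- kmeans_dtw(traj$matrix, K = 4, n_init = 10, seed = 42)
fit
#> DTW K-means: 4 groups, 200 trajectories
#> inertia: 3092.38  iterations: 5  converged: TRUE
#> group sizes: 28, 55, 60, 57

round(group_mean_trajectories(traj$matrix, fit$labels)[, c(1, 7, 13)], 1)
#>        day1 day7 day13
#> group1  1.9  2.1   1.5     # persistently low
#> group2  3.2  5.9   8.7     # increasing
#> group3  8.4  5.5   3.2     # decreasing
#> group4  9.9 10.2  10.2     # persistently high
```

Groups are numbered by ascending early (days 1–3) severity, so Group 1
is always the lowest-starting trajectory.  Against the generator's
ground truth this fit has adjusted Rand index 1.0.  Outcome association
and per-group PSH odds:

```r
outcomes <- cohort$outcomes[match(names(fit$labels), cohort$outcomes$patient_id), ]
outcome_summary(outcomes[c("patient_id", "psh_case", "dlt", "icu_los")], fit$labels)
#>   variable        type                test statistic      p_value significant
#> 1 psh_case categorical pearson_chi_squared     23.59 3.034964e-05        TRUE
#> 2      dlt  continuous       one_way_anova     96.04 2.842088e-38        TRUE
#> 3  icu_los  continuous       one_way_anova      6.53 3.142935e-04        TRUE

group_odds(crosstab(fit$labels, outcomes$psh_case), positive = "TRUE")
#>   group positives negatives  odds  lower upper ci_defined
#> 1     1         5        23 0.217 0.0826 0.572       TRUE
#> 2     2        26        29 0.897 0.5281 1.522       TRUE
#> 3     3        19        41 0.463 0.2690 0.798       TRUE
#> 4     4        38        19 2.000 1.1531 3.469       TRUE
```

The persistently-low group has PSH odds well below 1, the
persistently-high group well above — the pattern the trajectory
phenotype is designed to surface.  Admission predictors, screened and
then selected forward-stepwise into a multinomial model (reference
Group 1):

```r
covs <- cohort$covariates[match(names(fit$labels), cohort$covariates$patient_id), ]
scr  <- univariate_screen(covs, fit$labels,
                          types = c(age = "continuous", bmi = "continuous",
                                    mgcs = "continuous", sex = "categorical"))
st   <- forward_stepwise(covs, fit$labels, scr$feature[scr$selected], reference = "1")
subset(odds_ratios(st$model), feature == "age")
#>   group feature  estimate    or lower upper p_value reliable
#> 4     2     age -0.038909 0.962 0.932 0.992  0.0141     TRUE
#> 5     3     age  0.000364 1.000 0.973 1.029  0.9795     TRUE
#> 6     4     age -0.038245 0.962 0.933 0.993  0.0173     TRUE
```

Age and motor GCS survive selection; each additional year of age
lowers the odds of membership in the high-severity groups by about 4%
relative to the persistently-low group, mirroring the younger-age risk
gradient reported for post-TBI dysautonomia.

A command-line front end over the same functions is installed at
`inst/scripts/psh_pipeline.R` with `simulate`, `score`, `cluster`,
`associate` and `fit` subcommands.

## Method notes

See the methods vignette (`vignettes/trajectory-phenotyping.Rmd`) for
the scoring conventions, the DTW/DBA and model-selection details, the
regression design, what the synthetic generator does and does not
emulate, and known limitations — including a documented failure mode of
automatic elbow selection on these data.
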