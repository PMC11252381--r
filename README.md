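# sustainr

Subtype and stage inference for regional gray-matter-volume loss from
cross-sectional cohorts.

Progressive brain disorders such as schizophrenia show heterogeneous
patterns of gray-matter loss. Given only single-time-point ROI volume
tables from many subjects, `sustainr` infers *progression subtypes* —
groups of patients sharing an ordered sequence of regional volume-loss
events — and places every patient at a *stage* along their subtype's
sequence. The package is a complete, tested R implementation of the
z-score event-based subtype-and-stage model (SuStaIn-style) together
with the surrounding analysis pipeline used in multi-site neuroimaging
studies, plus a synthetic-cohort generator so the whole pipeline can be
validated without access to protected patient data.

## The model

An *event* is biomarker b crossing a severity waypoint z ∈ {1, 2, 3},
measured as a normative z-score (sign-flipped so higher z = more volume
loss). A subtype's *trajectory* S is an ordering of the E = 17 × 3 = 51
events (each biomarker crosses z = 1 before 2 before 3). The expected
z-score g(S, k, b) at stage k interpolates linearly through the
biomarker's waypoint positions, ending at z_max = 5. A subject with
z-row **z** has stage-marginal likelihood

    P(z | S) = (1/(E+1)) Σ_{k=0..E} Π_b N(z_b ; g(S, k, b), σ_b²),  σ_b = 1

and the cohort is a K-component mixture over trajectories with
fractions f_c. Sequences are estimated by multi-start EM with greedy
event repositioning, a hierarchical subtype-splitting construction, and
Metropolis–Hastings refinement over event orderings; K is selected by
two-fold cross-validated Dice label consistency (with the Hopkins
statistic testing whether clustering exists at all).

## Pipeline

| stage | function | what it does |
|---|---|---|
| simulate | `generate_cohort()`, `generate_clinical()` | multi-site cohort with planted trajectories |
| harmonize | `harmonize()` | covariate residualization → ComBat → normative z-scores → 5-SD outlier filter |
| cluster tendency | `hopkins_statistic()` | Hopkins H with Beta(m,m) verdict |
| select K | `select_K()` | cross-validated Dice consistency curve |
| fit | `sustain_fit()` | EM + hierarchical splits + MCMC |
| assign | `sustain_assign()` | subtype probabilities, hard labels, stages |
| characterize | `stage_correlates()`, `symptom_trajectory()`, `intersubtype_morphometry()`, `generalization_check()` | downstream statistics |

`run_pipeline(run_config(...))` chains all stages with one master seed
and writes TSV/JSON artifacts plus a digest manifest;
`inst/cli/sustainr` is a thin command-line front-end.

## Worked example

```r
library(sustainr)

spec <- sustain_spec()                      # 17 ROIs x z = 1,2,3; z_max 5
cfg  <- sim_config(n_patients = 800, n_controls = 800, seed = 11)
cohort <- generate_cohort(cfg)

h <- harmonize(strip_truth(cohort), apply_outlier_filter = FALSE)
Z <- as.matrix(h$z)[!h$control_mask, ]      # patients x 17 z-scores

model <- sustain_fit(Z, K = 2, spec,
                     sustain_settings(n_starts = 5, n_iter = 10000,
                                      split_restarts = 5), seed = 42)
model
#> event-based subtype model: K = 2 | fractions: 0.624/0.376 | loglik: -20815.2
#> MCMC archive: 10000 iterations

a <- sustain_assign(Z, model, spec)
table(a$table$subtype)
#>   1   2
#> 521 279
```

The mixture fractions (0.624/0.376) recover the planted 0.62/0.38
subtype composition; the recovered sequences match the planted
cortical-first and subcortical-first trajectories with Kendall tau ≈
0.93 and 0.90, and inferred stages correlate with planted stages at
Spearman ≈ 0.97 (console output from the run with seeds 11/42, the same
configuration exercised by the test suite).

## Layout

```
R/            implementation (atlas, events, simulate, harmonize,
              sustain, selection, characterize, pipeline)
src/          RcppArmadillo likelihood/search kernels
tests/        testthat suite (unit, property and end-to-end)
scripts/      acceptance.R
vignettes/    methods vignette
inst/cli/     command-line front-end
```
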