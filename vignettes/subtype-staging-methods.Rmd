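---
title: "Subtype and stage inference for regional gray-matter loss: models and methods"
author: "sustainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainr)
```

## The problem

Cross-sectional structural MRI cannot observe disease progression
directly, but a large cross-sectional cohort samples many points along
the (unobserved) progression of each patient. The z-score event-based
model exploits this: it assumes each patient belongs to one of K
*subtypes*, each defined by an ordered sequence of *events*, and sits at
an unknown *stage* along that sequence. An event is a regional biomarker
(here, one of 17 merged gray-matter-volume regions) crossing a severity
waypoint expressed as a normative z-score (z = 1, 2, 3 by default). With
B = 17 biomarkers and 3 waypoints each, a trajectory is an ordering of
E = 51 events, constrained so each biomarker crosses z = 1 before z = 2
before z = 3.

## Normative z-scores

Raw ROI volumes from multiple sites are converted to normative deviations
in a fixed composition:

1. **Residualization.** Per ROI, OLS regression of volume on sex, age,
   age squared, site and total intracranial volume; residuals retained.
   Coefficients are estimated on the pooled sample by default (the
   control-only alternative is available via `controls_only = TRUE`); published
   workflows of this kind rarely state which sample the coefficients
   come from, and on balanced simulated data the two differ negligibly.
2. **ComBat.** Empirical-Bayes location/scale batch adjustment across
   sites (the `sva` implementation), run after the site regression —
   mirroring the order in which multi-site harmonization protocols list
   the two steps, despite the partial redundancy.
3. **Z-scoring.** Per ROI, `z = (value - control mean) / control SD`,
   multiplied by −1 so larger z means more volume loss. Known normative
   parameters can be supplied instead of control estimates (used when
   staging unseen data against a trained normative model, and in tests
   with noise-free planted deviations, where an empirical control SD of
   zero would be undefined).
4. **Outlier filter.** Subjects with any regional deviation beyond 5 SD
   (two-sided, on the signed flipped z) are dropped and reported.

OLS residualization is exactly idempotent (residuals are orthogonal to
the design), but empirical-Bayes shrinkage leaves O(1/sqrt(n)) residual
batch means, so the pipeline as a whole is idempotent only up to
sampling noise — the property test asserts it at that tolerance.

## The event-based likelihood

For a subtype with sequence S, the expected z-score of biomarker b at
stage k is the piecewise-linear interpolant through (0, 0), the
biomarker's waypoint positions in S, and (E, z_max) with z_max = 5 (a
stricter replication setting uses 4). When a biomarker's last waypoint
falls at position E the z_max anchor is dropped to keep the interpolant
well defined. Measurement noise is Gaussian with sigma = 1 per biomarker
— inputs are normative z-scores, and no per-biomarker noise estimates
exist. Stages carry a uniform prior over 0..E, so a subject's likelihood
under a sequence is the stage-averaged product of normal densities,
computed in log space. Mixture fractions weight the K subtypes.

## Fitting

* **EM sequence search** (`optimize_sequences_em`): from random valid
  initial sequences, alternate responsibilities, fraction updates, and
  greedy single-event repositioning (remove an event, reinsert it at the
  best position that preserves within-biomarker threshold order).
  Single-event reinsertion is used rather than pairwise swaps because it
  preserves the threshold-order constraint by construction. The
  sequence update is a *generalized* M-step: two greedy sweeps per EM
  iteration (full convergence on the first pass); any improvement
  suffices for EM monotonicity, and full per-iteration convergence
  wastes sweeps that the next E-step would undo. Subjects with
  responsibility below 1e-3 for a subtype are omitted from that
  subtype's greedy search (their gradient contribution is negligible);
  the EM objective itself is always evaluated on everyone.
* **Hierarchical construction** (`fit_hierarchy`): the K-subtype model
  grows from K−1 by tentatively splitting each subtype. Candidate
  partitions of the parent's subjects are (i) a k-means split of the
  subjects' within-row deficit *rank profiles* and (ii) random binary
  partitions (default 10 restarts per parent, following the reference
  formulation of this model family; the restart count is our choice);
  each candidate is scored with a short (2-iteration) EM and only the
  best is fully refined. The rank-profile candidate was added after
  purely random partitions proved insufficient: both children then
  start near the parent's sequence, and the subsequent EM converges to
  a symmetric "blend" local optimum (each sequence an average of the
  planted trajectories) that neither longer EM nor the MCMC stage
  escapes, measurably below the likelihood of the separated solution.
  A subject's rank profile — the order of its regional deficits — is
  invariant to stage and carries exactly the information that
  distinguishes subtypes, so clustering on it reliably breaks that
  symmetry; the random partitions remain as additional candidates and
  the likelihood decides.
* **MCMC refinement** (`mcmc_sequences`): Metropolis-Hastings whose
  proposal removes one event of one subtype's sequence and reinserts it
  uniformly among order-preserving positions; acceptance
  min(1, exp(Δ log-lik)). The full archive is retained; the final
  sequences are the maximum-likelihood sample. MCMC runs only at the
  final K of the hierarchy — the chains of intermediate levels would be
  discarded anyway.
* **Assignment** (`sustain_assign`): subtype probabilities proportional
  to fraction × marginal likelihood, averaged over 100 evenly spaced
  archive draws (conventions in this model family differ between
  averaging the full archive and using the ML sample alone; thinning
  makes the average cheap and stable). The stage is the maximum-likelihood stage under the hard
  subtype's ML sequence. All argmax ties resolve toward the lower
  index/stage.

Default settings are scaled for a single CPU (5 starts, 10,000 MCMC
iterations); the full-scale analysis uses 25 starts and 100,000
iterations via `sustain_settings()`.

## Choosing K

The Hopkins statistic (uniform probes over the bounding box vs sampled
real points, H = Σu/(Σu+Σw), Beta(m, m) null) answers whether the
z-score cloud is clustered at all. The number of subtypes is then chosen
by two-fold cross-validated label consistency: patients are split in
half, a model hierarchy is fitted on each fold, both fold models label
*all* patients, and the two labelings are compared with the Dice
coefficient after optimal label matching (exhaustive over K! for the
small K used here). The overall Dice is the subject-weighted mean of
per-subtype Dice values — a choice among several defensible multi-class
aggregations, picked because it equals the fraction of subjects keeping
their label and is therefore directly interpretable. K = 1 is excluded
(its Dice is trivially 1); ten repeats by default, median aggregated,
ties toward smaller K. By default each fold model labels all
individuals, so the Dice measures consistency over the whole cohort; a
held-out-only mode is available.

## Downstream characterization

Spearman correlations (with Benjamini–Hochberg FDR across measures) link
the inferred stage to regional z-scores, illness duration and symptom
scores. Illness duration is binned early ≤ 2 y, middle (2, 10] y, late
> 10 y; both "<2 years" and "≤2 years" conventions appear for the
early boundary in this literature, and the default follows the
inclusive version with the strict variant selectable. Symptom trajectories: one-way ANOVA across bins
within subtype, plus per-bin two-sample t-tests between subtypes on
residuals after regressing out age, sex and stage (uncorrected, as
reported there). Regional morphometry contrasts: pooled-variance
t-tests, Cohen's d (subtype 1 − subtype 2), and Holm adjustment for the
family-wise error — Holm is valid under arbitrary dependence and
uniformly dominates Bonferroni.
Generalization: a model trained on a sub-cohort labels the unseen
subjects, and agreement plus stage Spearman against the full-data model
are reported after label matching.

## The synthetic cohort

The generator plants the structure the analysis assumes: two
trajectories (cortical-first from Broca's area; subcortical-first from
the hippocampus) laid out in waypoint waves, subtype fractions
0.62/0.38, uniform stage occupancy (the stage occupancy of a real cohort is not
known a priori, so uniform is an explicit assumption),
unit control SD so planted deviations are exact z units, Gaussian noise,
three sites with additive shifts ±0.3 control SD and noise scale factors
0.9–1.1 (detectable but realistic for testing ComBat), and covariate
effects of age, age², sex and TIV. Illness duration is
Gamma(1.2, scale 5) + 0.06 × stage years, targeting the weak
stage–duration association (Spearman ≈ 0.1) reported for the real
cohort; symptom subscales are linear in duration with subtype-specific
slopes — negative and depression/anxiety symptoms worsen only in
subtype 1 (+0.15 and +0.10 points/yr), positive symptoms decline in both
(−0.25/yr) — the qualitative clinical pattern the analysis is
designed to detect. The subscale
`sd` values are residual spreads about the duration trend, with the
trend-carrying subscales calibrated so the planted worsening is
detectable at the design's sample size; cohort-level SDs are larger
because they also carry duration spread and subtype mixing.
Simulation truth lives in `true_*` columns that every inference stage
strips on entry.

What the generator does *not* emulate: realistic inter-regional
covariance beyond the planted trajectories, non-Gaussian site or scanner
artifacts, missing data, medication effects, or the real cohort's stage
occupancy. Passing tests therefore demonstrate that the machinery
recovers planted structure under the model's own assumptions — not
that any particular cohort's estimates are reproduced; real clinical
datasets of this kind are typically access-protected.

## Numerical choices

Log-likelihoods are computed via a scaled cross-product and a row-wise
log-sum-exp that skips terms more than 34 log-units below the row
maximum (below double precision of the sum). The greedy search accepts
moves improving the weighted log-likelihood by more than 1e-6; EM stops
on a 0.01 log-likelihood plateau or after 10 iterations. ComBat is the
parametric empirical-Bayes variant. The MCMC loop draws from R's RNG, so
`set.seed()` makes chains bit-reproducible; every pipeline stage derives
a child seed from one master seed. Problem sizes in the shipped tests
and the acceptance script — 800 patients + 800 controls, 5 EM starts,
10,000 MCMC iterations, 3 Dice repeats over K ∈ {2,3,4}, and 3
starts / 3 split restarts inside the cross-validated model selection —
are the package's scaled defaults for a single-CPU run; the full-scale
settings (25 starts, 100,000 iterations, 10 repeats, K up to 6) are one
`sustain_settings()` call away.

## Known limitations

* The greedy + MCMC search is a heuristic over a (51!)-sized constrained
  space; only the ≤4-event toy models are verified against exhaustive
  enumeration.
* Stage 0 subjects are uninformative about subtype membership; subtype
  accuracy is therefore evaluated past stage 10, and mixture fractions —
  not hard-label counts — estimate the subtype composition.
* A 17-event single-waypoint mode (`waypoints = 1`) is provided because
  staging figures in this literature sometimes condense the event grid
  to one row per region; the default is the 51-event model.
* No continuous-time variant, no per-biomarker Gaussian-mixture event
  model, no covariate-adjusted staging, no ComBat-GAM.
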