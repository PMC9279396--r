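---
title: "Semi-supervised EHR screening for undiagnosed BoPD: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised EHR screening for undiagnosed BoPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bopdscreen)
```

Borderline personality disorder (BoPD) is common, disabling and frequently
missed in routine care. Its EHR footprint, however, is characteristic:
mood-disorder and bipolar codes (with which BoPD is often confused),
suicidal ideation and intentional self-harm, trauma- and stressor-related
diagnoses, substance use, and unstable, emergency-heavy patterns of
service use. `bopdscreen` operationalizes that footprint in two steps: a
deterministic rule engine that narrows an EHR population to a *potential
BoPD cohort*, and a semi-supervised classifier that ranks the cohort by
the probability of being a "most likely BoPD" case as a clinical expert
would judge it from the structured record.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic-data generator used for testing, and the places
where the design was genuinely open and a choice had to be made.

## The selection rules

All rule logic operates on normalized codes (uppercase, dots stripped —
`F60.3` and `f603` are the same code) and on encounter *discharge dates*;
an event belongs to the study period iff
`study_start <= discharge_date <= study_end`, both bounds inclusive. A
patient enters the potential cohort when all of the following hold:

1. **Sufficient history** — at least `min_encounter_dates` (default 5)
   distinct discharge dates, or at least `min_emergency_dates` (default
   2) distinct emergency discharge dates, in the study period. Encounters
   carrying no diagnosis code are ignored; two visits on one date count
   once. We count encounters with *any* diagnosis code, not only
   mental-disorder codes — the only stated restriction in the source
   algorithm is that undocumented encounters do not count.
2. **Qualifying diagnosis** — at least one ICD-10-CM diagnosis in the
   BoPD-associated CCSR categories (MBD002–MBD009 singles, MBD012/MBD027
   suicidal/self-harm, MBD017–MBD025 substance), dated when the patient
   was 18–65 completed years old. Age is evaluated per diagnosis event at
   the encounter's discharge date, because the criterion anchors
   diagnoses, not patients, to the age window.
3. **Symptom rule** — bipolar (MBD003) or suicidal/self-harm codes
   present; otherwise at least `min_other_categories` (default 3)
   *category groups*. The eight substance categories collapse to one
   group and the two suicidal categories to one group, mirroring the
   category rows the rule is phrased on. Patients *with* bipolar or
   suicidal codes are not additionally required to reach 3 groups — this
   is what makes the Y2 sampling stratum (bipolar/suicidal but < 3
   groups) non-empty.
4. **Exclusions** — a BoPD code (ICD-10-CM `F60.3` or ICD-9-CM `301.83`)
   anywhere in the record, including before the study window, excludes
   (these patients are not "undiagnosed"); F01–F09 (mental disorders due
   to known physiological conditions) or F70–F79 (intellectual
   disabilities) inside the window exclude, matched on the 3-character
   ICD-10-CM category prefix.

The *EHR-diagnosed cohort* — the silver-positive source — flips the BoPD
code from exclusion to inclusion (F60.3 in the study period) and keeps the
history, age and organic/intellectual rules. Silver positives are the
diagnosed-cohort patients who still satisfy the symptom rule when every
F60.3 event is disregarded; a patient whose only mental-disorder code is
F60.3 itself contributes nothing to the re-profile and is dropped.

`select_potential_cohort()` returns the full per-patient rule trace and
the funnel of surviving counts per stage, because in practice the first
question about any computable phenotype is "where did my patients go".

## Chart-review sampling

Expert labels are expensive, so they are collected on stratified samples.
Strata cross gender × age band (18–39, 40–59, 60–65, taken at the last
study-period encounter) × history class (N / Y1 / Y2 as defined above).
Allocation is proportional with largest-remainder rounding — the source
algorithm does not state a rounding rule, and largest-remainder keeps
every stratum within one unit of its exact share. Paired train/test sets
are drawn as one stratified sample of `2n`, allocated by largest
remainder on `n` and doubled, then split evenly at random within each
stratum: this guarantees *identical* gender and age margins in the two
sets, the property reported for the real gold samples. (Whether the
original two samples were drawn jointly or sequentially is not stated; we
draw jointly because it reproduces the reported margin identity exactly.)
Patients with unknown/other gender are excluded from the sampling frame
before stratification.

Ratings use categories A (physical-primary), B (severe
psychotic/substance), C (unsure), D (possible), E (most likely BoPD),
with a classic-BoPD subflag allowed only on E. The binary target is
`category == "E"`.

## Features

All features are Boolean. Diagnosis features start from the codes with
patient-level prevalence ≥ `prevalence_cutoff` (default 0.05, inclusive)
in the diagnosed cohort *or* in the potential cohort — the two per-cohort
lists are combined as a union, which we read from the fact that combining
is described as enlarging the list. Codes are then partitioned into one
feature per non-empty (CCSR category × expert association rating) cell;
unrated codes default to `unsure`, unmapped codes go to a reserved
`UNMAPPED` category with a warning. Three deliberate choices:

- **F60.3 is never a feature.** It is ~100% prevalent among silver
  positives and structurally absent from the screening population, so as
  a feature it would let the main model memorize the silver label while
  carrying zero information at deployment.
- **Encounter-frequency bins** (high/median/low) are not defined in the
  source algorithm; we use tertiles of the distinct-discharge-date count
  in the training cohort, frozen into the feature spec so new data are
  binned deterministically. Counts exactly at a cutoff fall to the lower
  bin. Distinct dates (rather than raw encounters) keep the definition
  consistent with the history rule.
- **Gender stays in the model.** The screening decision applies only to
  `p_final`; no rule ever gates on gender directly.

Demographic bins (age band at last study-period encounter, female),
encounter-type presence flags and the frequency bins are always present
regardless of which diagnosis cells are non-empty.

## The three models and the combination rule

Every model is an L1-regularized logistic regression
(`train_l1_logreg()`, glmnet backend, unstandardized Boolean inputs).
The penalty is selected from a fixed grid of 13 log-spaced values
spanning `1` to `1e-6` by mean validation-fold AUROC over stratified
`cv_folds = 10` cross-validation; exact ties go to the stronger penalty
(the sparser model). The fixed grid makes penalty selection reproducible
across runs and seeds; six orders of magnitude comfortably bracket the
useful range for Boolean designs of a few hundred columns. Constant
columns are dropped with a warning before fitting.

- **Model 1 (seed)** is fit on the gold training set, E vs A–D.
- **Silver construction**: Model 1 scores the potential cohort minus the
  gold samples; patients with `p1 < 0.5` (strictly — a patient at exactly
  0.5 is not "predicted negative") form the negative pool, from which
  `floor(n_pos * gold_ratio_neg / gold_ratio_pos)` are drawn uniformly at
  random. The floor matches the published worked example
  (`floor(5961 * 162/66) = 14631`), and uniform sampling reflects
  "randomly selected".
- **Model 2 (main)** is fit on the silver set; **Model 3 (adjustment)**
  on the gold rows with categories E and B only, positive = E. The B
  category (severe psychotic/substance abuse) is the dominant source of
  false positives for a comorbidity-driven screener, which is why it
  gets a dedicated discriminator.
- **Combination**: `p_final = p2` if `p3 > 0.5`, else `p2 * p3`. A `p3`
  of exactly 0.5 falls to the multiplicative branch (the confident branch
  requires strict inequality). Consequences, all property-tested:
  `p_final <= p2`; the adjustment never creates a positive; `p_final` is
  nondecreasing in `p3` below 0.5.

A patient screens positive iff `p_final > decision_threshold` (default
0.5, strict).

## Evaluation

`auroc()` is the midrank Mann–Whitney statistic (ties count ½), so it is
invariant under strictly increasing transforms and satisfies
`auroc(s, y) + auroc(s, 1 - y) = 1`. Threshold metrics (accuracy, PPV,
sensitivity, specificity, classic sensitivity) come from the confusion
matrix at the decision threshold; classic sensitivity is computed only
over classic-flagged positives. Confidence intervals are percentile
bootstrap over `bootstrap_reps = 1000` row resamples of the test set
(the patient is the resampling unit); percentile rather than BCa because
no specific variant is mandated and percentile intervals are transparent
at these sample sizes. Replicates on which a metric is undefined — a
single-class resample, no predicted positives, no classic rows — are
skipped for that metric and counted in the report; a metric undefined on
more than half the replicates gets a missing interval rather than a
fabricated one.

## The synthetic-EHR generator

`generate_cohort()` emulates the structure the pipeline assumes, not any
real database's marginals. Each patient draws a latent class —
`bopd_like` (12%), `psychotic_substance` (7%), `physical_primary` (31%),
`other_mental` (18%), `healthy` (31%) — then a negative-binomial
encounter count (class means 11/10/7/6/2.5, dispersion 3, producing the
frequency spread the tertile bins rely on), class-specific
emergency/inpatient mixes, and 1–3 diagnosis codes per encounter from
class-conditional category distributions over a ~60-code miniature
CCSR-style table. `bopd_like` patients emit bipolar and suicidal codes at
elevated rates; 25% of them carry F60.3 in-period (becoming the diagnosed
cohort); small fractions of all classes carry organic/intellectual codes,
pre-period encounters, pre-period BoPD codes, and unknown gender, so the
exclusion and filtering paths are exercised. Expert ratings map the
latent class deterministically (bopd_like→E with a classic flag for the
top severity quintile, psychotic_substance→B, physical_primary→A,
other_mental→C/D, healthy→C) and are flipped to a random other category
with probability `rating_noise` (default 5%, a plausible single-rater
inconsistency level).

The class mixture and category weights were chosen so the potential
cohort's most-likely-BoPD fraction sits near the ~29% positive rate of
the real gold samples (observed 25–28% at n ≥ 2000) and so that every
rating category is populated in a 228-patient draw. What the generator
does *not* emulate: real ICD-10-CM marginal frequencies, code
co-occurrence beyond the latent class, temporal disease progression,
inter-site coding variation, and label noise that is correlated with the
features. Passing tests therefore demonstrate that the machinery is
correct and that the pipeline recovers planted class structure — not that
the published real-data operating characteristics transfer.

## Problem sizes and numerics

The test suite and the acceptance script run end-to-end pipelines at
4,000–8,000 synthetic patients with 228-patient gold samples, penalty
selection over 10 folds × 13 penalties, and 1,000 bootstrap replicates —
sizes at which every planted effect is comfortably detectable while a
full run stays in seconds. Rule-engine equivalence is checked against an
independently coded brute-force evaluator on 200 random small cohorts;
AUROC against brute-force pairwise comparison at `1e-12`; coefficient
sign recovery on planted sparse logistic models at n = 5,000 over 20
seeds; and the silver-benefit property (the main model matching or
beating the gold-only seed model out of sample) on a planted benchmark
with a 20× silver set carrying 10% label noise, averaged over 20 seeds.

Degenerate inputs are handled explicitly: single-class labels and
missing E/B categories are errors; constant features are dropped with a
warning; empty diagnosis tables, patients with no study-period events,
and empty strata produce well-defined all-false/zero results rather than
failures. All randomness flows through per-stage seeds derived from one
master seed, and every stochastic function restores the caller's RNG
state.

## Known limitations

- The screener is a *screening* tool: a high `p_final` prioritizes a
  chart for assessment, it does not diagnose.
- Real-data performance cannot be validated here; the original clinical
  database is proprietary, and the synthetic generator is deliberately
  structural rather than realistic.
- The rule engine requires ICD-10-CM; ICD-9-CM enters only through the
  301.83 exclusion, with no cross-walking.
- Single-expert labels: inter-rater variability is out of scope, and the
  rating-noise model is class-independent.
- The classifier seam is pluggable in principle, but L1 logistic
  regression is the only fitted and tested estimator — it won the
  original comparison on both performance and interpretability, and its
  sparse coefficients are the deployment artifact.
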