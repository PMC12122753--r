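---
title: "Segmenting diabetes claims cohorts before an emergency department visit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting diabetes claims cohorts before an emergency department visit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimslca)
```

## The analysis problem

Type 2 diabetes mellitus (T2DM) is an ambulatory care sensitive condition:
a substantial share of hospital admissions of T2DM patients could be
avoided under adequate outpatient care.  Emergency departments (EDs) sit
at the interface of the outpatient and inpatient sectors, so linked ED and
statutory-health-insurance claims data are a natural place to study which
care patterns precede an ED visit.  This package implements a complete,
reproducible pipeline for that question: cohort extraction with diagnosis
validation, construction of categorical guideline indicators over the year
before the index ED visit, missing-data imputation, latent class analysis
(LCA) with a multi-criterion selection and stability protocol, and class
profiling with odds-ratio regression.

Real claims data of this kind are access-restricted.  The package
therefore treats a synthetic claims generator as a first-class module:
every downstream stage is developed and tested against data with known
latent structure.

## Cohort extraction and validation

Claims billing in the German statutory system is organised by calendar
quarter, which drives all window arithmetic.  Each patient's **index
visit** is the earliest ED visit of the index year (2016); "two years
prior" means the 8 calendar quarters strictly before the index quarter,
and "one year prior" the 4 quarters before it (the index quarter itself is
always excluded).

Extraction proceeds in three steps:

1. **Candidates** — any patient with at least one diabetes code (stems
   E10–E14) among outpatient diagnoses carrying the qualifier "confirmed"
   or "condition after" in the 8-quarter window, ED diagnoses of the index
   year, or the main hospital diagnosis.  The qualifier filter applies to
   outpatient codes only; facility diagnoses are taken at face value.
2. **Validation** — four conditions tested in order, first hit wins:
   (1) diabetes coded in at least two distinct lookback quarters (an
   M2Q-style repeated-documentation criterion relaxed to two years);
   (2) one lookback quarter plus a diabetes ED diagnosis; (3) any single
   diabetes code plus an insulin or oral antidiabetic (OAD) prescription
   in the lookback; (4) diabetes as main hospital diagnosis.  Quarters
   need not be consecutive, and diagnosis and prescription may sit in
   different quarters.  Because the conditions are ordered, condition 2 in
   practice means *exactly* one qualifying outpatient quarter.
3. **Type allocation** — the allocation algorithm of the source analysis
   is not publicly documented, so the package ships a deterministic
   reconstruction from its stated ingredients: type 1 iff E10-coding
   without E11 under insulin-only therapy, or type-1 DMP enrolment without
   the type-2 programme; otherwise type 2 iff E11 coded, OAD prescribed or
   type-2 DMP attended; E12–E14-only coders under insulin-only therapy are
   "other"; the remainder "unclear".  Users can bypass the rule by
   post-processing the evidence columns that `build_cohort()` returns.
   This rule should be understood as a documented stand-in, not as the
   original algorithm.

The final cohort additionally requires at least one documented outpatient
case.  ICD matching is prefix-based on dot-stripped codes ("E11" matches
"E11.2" and "E112").

## Indicator construction

Eleven categorical indicators are built per patient (see
`indicator_levels()` for the exact coding): sex; age in four bands (ages
are visit year minus birth year — claims carry no birth dates — averaged
over visits and rounded half *up*, so a mean of 70.5 falls into 71–85);
the number of diabetes complication *groups* (metabolic, eye, kidney,
neuro-vascular, multiple) read off the fourth digit of E10–E14 codes, with
the default digit map .0/.1 metabolic, .2 kidney, .3 eye, .4/.5
neuro-vascular, .7 multiple, and .6/.8/.9 contributing no group;
diabetes medication in four levels (none / OAD only / insulin only /
both); and seven quarter-count indicators (GP, general specialist,
specialised specialist contacts; HbA1c, microalbuminuria, creatinine
measurements; fundus examination), each counting *distinct* quarters with
a matching event — flat rates are billed once per quarter, so the quarter
count is the finest defensible contact measure — and categorised 0 / 1–2 /
3–4.

Two conventions matter for missingness.  An event that is absent while the
patient appears at least once in the outpatient data is a genuine zero
(category 0); a patient entirely absent from the outpatient data gets
missing utilisation indicators.  The medication indicator is missing — not
"no medication" — for patients of a region whose SHI physician association
does not transmit prescription data.

The Charlson comorbidity index uses the Quan ICD-10 prefix mapping with
the original weights and the usual severity hierarchies (complicated
diabetes over uncomplicated, moderate/severe liver disease over mild,
metastatic tumour over any malignancy).  The source analysis does not
state the Charlson window; this package uses the same one-year lookback as
the other indicators, which keeps all indicator inputs on one observation
window.  Billing-code sets for the laboratory indicators default to
synthetic placeholder codes because real outpatient billing numbers are
regionally versioned; supply your own via `code_config()`.

## Imputation

Missing categories are filled by iterative, fully conditional
random-forest imputation: initialise with the per-variable mode, then
visit variables in order of increasing missingness, each time training a
classification forest (100 trees, majority vote, `ranger`) of the
variable on all others and predicting its missing cells.  The loop stops
after at most 10 iterations — the iteration count named by the source
method is read as a cap, not a fixed count — or as soon as the fraction of
imputed cells that changed *increases* relative to the previous iteration,
a proxy for the out-of-bag stopping rule of the reference method.
Observed cells are never modified, and per-iteration forest seeds are
derived from the master seed, so imputation is reproducible.  No multiple
imputation is performed; the analysis design calls for single imputation.

## The latent class model

For indicators $x_{i1},\dots,x_{iJ}$ the $K$-class model is a finite
mixture of independent multinomials,
$P(x_i) = \sum_k \pi_k \prod_j \theta_{k,j,x_{ij}}$, estimated by EM.
Implementation choices:

* Duplicate response patterns are collapsed with multiplicity weights;
  the likelihood is exact and the E/M steps scale with the number of
  distinct patterns, not the sample size.
* The E-step runs in log space; the M-step floors probabilities at
  $10^{-10}$ and renormalises, preventing log-domain underflow on empty
  cells.  The floor is far below any quantity of scientific interest.
* `restarts` random-responsibility initialisations (restart $r$ seeds
  from the master seed plus $r$); the best log-likelihood wins, ties going
  to the lower restart index.  Convergence is declared when the relative
  log-likelihood change drops below `tol` (default $10^{-8}$ for single
  fits, $10^{-7}$ on the selection grid, where many fits are run).
* $K = 1$ is computed in closed form (independent multinomial marginals).
* Classes are reported in a canonical order of ascending disease-stage
  score (the mean expected category code of the medication and
  complication indicators), so class 1 is always the earliest-stage class.
  Stability comparisons never rely on this ordering; they use
  label-invariant indices or explicit maximum-agreement matching.

Fit and separation statistics: `BIC = -2ℓ + p log n` with
`p = (K-1) + K Σ_j (C_j - 1)`; posterior entropy
`EN = -Σ_i Σ_k τ_ik log τ_ik`; scaled relative entropy
`E = 1 - EN / (n log K)`; and `ICL = BIC + 2·EN`.  The per-indicator
discriminatory-power ranking uses the mixture-weighted Kullback–Leibler
divergence of each indicator's class-conditional distribution from its
mixture marginal — the metric of the source analysis is not publicly
specified, so this definition is a documented, replaceable default.

## Model selection and validation

The independence screen computes Spearman rank correlations on the
ordinal category codes (the binary sex indicator participates as a
two-level code) and flags pairs at or above 0.50, the conventional
threshold for local-independence violations.  Within a flagged pair the
variable with the larger mean absolute correlation to all other variables
is dropped.  Profiles within 0.02 of each other are treated as tied, and
the tie goes against the later column: a redundant noisy copy of an
earlier indicator carries an expectation-identical correlation profile to
its source, so without the tolerance the choice would be decided by
sampling noise rather than by anything scientific.

Selection then runs on a 70 % training split (`split_sample()`, seeded).
Models for $K = 1$ to $10$ are fitted and three candidates derived: the
BIC elbow (interior $K$ maximising the second difference of the BIC
sequence, ties to the smaller $K$), the maximum average silhouette width,
and the minimum ICL.  The prose rule "under consideration of" the three
criteria is formalised as: choose the smallest $K$ endorsed by at least
two criteria, else fall back to the maximum-ASW candidate; then enforce
the constraints (smallest class share ≥ 5 %, smallest class-average MAP
posterior ≥ 0.80), moving to the next candidate by descending ASW on
violation.  Every decision is recorded in a textual trace.

The ASW uses simple-matching distance (fraction of disagreeing
indicators).  Under that distance the mean distance from a point to a
cluster is a function of per-cluster category counts only, so the package
computes the silhouette exactly in $O(nJK)$ without a distance matrix; a
seeded subsample cap (default 10,000) is retained for interface
compatibility and is also what keeps the brute-force test oracle feasible.
Members of singleton clusters score 0 by convention.

Partition stability offers both resampling routes, because the source
protocol does not pin down which produced its published indices:
`bootstrap_stability()` refits on bootstrap resamples and compares MAP
partitions with the reference on the resampled rows; and
`holdout_confirmation()` classifies the 30 % validation split with the
training model, refits fresh on the validation data, and compares.  Both
report the adjusted Rand index (pair-counting, expectation-adjusted) and
the pairwise co-assignment Jaccard index, which are label-invariant.

## The synthetic generator

The generator has two layers.  The **profile layer** samples indicator
matrices directly from a `latent_class_spec` (mixture weights,
class-conditional category distributions, outcome log-odds).  The
**claims layer** is a constrained inverse of the indicator construction:
it emits patients, diagnoses, billing events, prescriptions, ED visits
and DMP rows such that `build_indicator_matrix()` reproduces the input
profiles *cell for cell*, choosing uniformly among event placements
consistent with each category (which lookback quarters carry a code, how
many distinct quarters within the category's range).  Distractor patients
come in three archetypes, one per rejection path: type-1-only patients
(E10 coding, insulin, T1DMP), single-quarter coders with no
prescriptions, and patients without any diabetes code.

The default specification (`default_class_spec()`) plants three classes
with weights (0.365, 0.261, 0.374) along the narrative "early stage /
high utilisation", "progressing stage / low utilisation", "progressed
stage / high utilisation".  Two requirements shaped the preset: the
classes must be separated well enough that parameter recovery and the
full selection protocol are meaningful test subjects, and the
between-class structure must not itself push indicator pairs over the
0.50 correlation threshold (strongly separated indicators that all load
on one severity gradient correlate mechanically — the "salsa" pattern).
The preset therefore lets each indicator load mainly on one of three
class-contrast directions (class 1, 2 or 3 versus the rest), and its
strengths were calibrated once against a Bayes-oracle classifier built
from the true parameters (oracle ARI ≈ 0.96, all non-planted pairwise
correlations ≤ ≈0.48) rather than against the EM implementation under
test.  Category distributions stay close to published descriptive
margins where that is compatible with separation.  The creatinine
indicator is generated as a noisy copy of HbA1c (copy probability 0.45,
giving an overall correlation of ≈0.63 once the shared class structure is
included), planting exactly the local-independence violation the screen
is meant to find.  Outcome intercepts reproduce a 60.8 % admission and
22.7 % recurrent-visit rate in the reference class, with per-class
log-odds offsets targeting admission odds ratios of 1.27 and 1.38 and
recurrent-visit odds ratios of 1.03 and 1.17.

What the generator does *not* emulate: realistic ICD code frequency
spectra beyond small illustrative pools, billing law beyond quarter
granularity, continuous laboratory values (claims carry none), and —
because no joint age × class × outcome distribution is published — any
age-confounded outcome mechanism by default (age effects on outcomes can
be added through the spec, but there is no data-anchored default).
Passing tests on synthetic data therefore demonstrate correctness of the
pipeline's logic and estimation, not performance on real claims.

A region whose physician association does not transmit prescription data
is emulated by `inject_missing_prescriptions()`: a seeded ~20.4 % of
patients are reassigned to a dedicated region, their prescription rows
removed and their medication indicator made missing.

## Problem sizes and reproducibility

All stochastic stages take explicit integer seeds; derived sub-seeds stay
within 32-bit range.  The test suite exercises parameter recovery at
n = 5,000 over ten seeds, the full selection pipeline at n = 10,000 over
ten seeds (split 0.7, K = 1…10, five restarts per fit), the cohort round
trip on a 360-patient labelled fixture, and oracle comparisons on
fixtures of at most 50 rows, sizes chosen to make the properties sharp
while keeping a full run comfortable on a laptop.  `scripts/acceptance.R`
re-runs the headline computations from scratch for a given seed.

## Known limitations

* The type-allocation rule and the complication-group digit map are
  reconstructions of undocumented components and are configurable for
  that reason.
* The discriminatory-power metric is a KL-based stand-in.
* Logistic odds ratios use Wald intervals (which reproduce the published
  intervals from aggregated counts); profile-likelihood intervals are not
  implemented.
* Diagnosis-per-visit summaries report the plain ratio of coded
  diagnoses to visits; published averages computed on other bases may
  differ slightly.
* The pipeline performs single imputation; uncertainty from imputation is
  not propagated.
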