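# claimslca

Latent class segmentation of type 2 diabetes mellitus (T2DM) patients in
statutory-health-insurance claims data, anchored on an emergency department
(ED) visit.

## What this package is for

Diabetes is an ambulatory care sensitive condition: many hospital
admissions of T2DM patients are considered avoidable under adequate,
guideline-based outpatient care.  Analysts working with linked ED and
outpatient claims data can use this package to

1. extract and **validate a T2DM cohort** from long-format claims tables
   (outpatient diagnoses with coding qualifiers, billing events, drug
   prescriptions, disease-management-programme enrolment, ED visits with
   hospital discharge diagnoses);
2. build **categorical guideline indicators** over the year before each
   patient's first ED visit — disease stage (complication groups, diabetes
   medication), physician-contact intensity by specialty group, and
   process-quality markers (HbA1c, microalbuminuria and creatinine
   measurements, fundus examination) counted per billing quarter;
3. impute missing indicators with **iterative random-forest imputation**;
4. fit **latent class models** (finite mixtures of independent
   multinomials) by maximum likelihood and select the number of classes
   with a multi-criterion protocol; and
5. **profile the classes**: response distributions, top coded diagnoses,
   Charlson comorbidity, and univariate / age-adjusted logistic odds
   ratios for recurrent ED visits and inpatient admission.

Because real claims data of this kind are access-restricted, the package
ships a **synthetic claims generator** with planted latent classes, known
outcome effects, cohort distractors and a non-transmitting prescription
region, so the entire pipeline is testable end to end.

## The model

For patient *i* with categorical indicators *x\_{i1}, …, x\_{iJ}*, the
K-class latent class model assumes local independence within class:

```
P(x_i) = Σ_k π_k Π_j θ_{k, j, x_ij}
```

with mixture weights π and item-response probabilities θ estimated by EM.
Model choice over K = 1…10 combines the **BIC elbow** (maximum second
difference of the BIC curve), the **maximum average silhouette width**
(simple-matching distance) and the **minimum ICL** (ICL = BIC + 2·EN,
where EN is the posterior entropy), subject to a smallest class share of
at least 5 % and a class-average posterior of at least 0.80.  Partition
stability is validated with the adjusted Rand and Jaccard indices on
bootstrap refits and on a 30 % holdout.

## Worked example

```r
library(claimslca)

res <- run_pipeline(n_patients = 2000, n_distractors = 100, seed = 11,
                    Kmax = 6, restarts = 5)
res$attrition
#>        eligible     any_dm_code    validated_dm            t2dm outpatient_case
#>            2100            2067            2034            2000            2000
writeLines(res$selection$trace)
#> candidates: BIC elbow K=3, max ASW K=2, min ICL K=3
#> majority of criteria endorse K=3
#> K=3 satisfies class-share >= 0.05 and posterior >= 0.80
round(res$profiles$shares, 3)
#> class_1 class_2 class_3
#>   0.368   0.248   0.384
```

The attrition funnel shows the three-step cohort validation: 100 planted
distractor patients drop in equal parts at the candidate step (no diabetes
code), the validation step (single-quarter coders) and the type-allocation
step (type 1 diabetes).  The selection trace records which of the three
criteria agreed on the number of classes, and the shares recover the
planted mixture weights (0.365 / 0.261 / 0.374).

Odds ratios can also be computed directly from an aggregated
class-by-outcome table; with per-class admission counts this reproduces a
published worked example to two decimals:

```r
odds_ratio_from_counts(events = c(9002, 7023, 10365),
                       non_events = c(5795, 3556, 4820))[, c("or", "ci_low", "ci_high")]
#>     or ci_low ci_high
#> 1 1.27   1.21    1.34
#> 2 1.38   1.32    1.45
```

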