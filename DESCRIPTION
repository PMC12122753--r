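Package: claimslca
Title: Latent Class Segmentation of Diabetes Claims Cohorts Before an
    Emergency Department Visit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting type 2 diabetes mellitus (T2DM) patients in
    statutory-health-insurance claims data by their outpatient health care
    utilisation prior to an emergency department (ED) visit.  The package
    covers the full analysis pipeline: a synthetic claims generator with
    planted latent classes, quarter-based cohort extraction with stepwise
    diagnosis validation (an M2Q-style criterion), construction of categorical
    guideline indicators including the Charlson comorbidity index, iterative
    random-forest imputation of missing indicators, maximum-likelihood latent
    class analysis of categorical indicators via the EM algorithm, model
    selection combining the BIC elbow heuristic, average silhouette width and
    the integrated completed likelihood with class-size and posterior
    constraints, partition-stability validation via the adjusted Rand and
    Jaccard indices, and class profiling with univariate and age-adjusted
    logistic odds-ratio regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
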