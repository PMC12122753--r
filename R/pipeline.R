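# End-to-end orchestration: synthetic study -> cohort -> indicators ->
# imputation -> independence screen -> split -> model grid -> selection ->
# stability -> profiling and regression.

#' Run the full segmentation pipeline on a synthetic study
#'
#' Generates a synthetic claims study, extracts and validates the T2DM
#' cohort, builds and imputes the indicator matrix, screens for
#' local-independence violations, selects the number of latent classes on
#' a 0.7 training split, confirms the partition on the validation split,
#' applies the chosen model to the whole cohort and profiles the classes
#' including odds-ratio regression of admission and recurrent-visit
#' outcomes.
#'
#' @param n_patients cohort patients to simulate.
#' @param n_distractors non-qualifying patients to add.
#' @param seed master seed for every random stage.
#' @param spec generator specification (default [default_class_spec()]).
#' @param Kmax largest class count on the grid.
#' @param restarts EM restarts per grid fit.
#' @param split_ratio training fraction.
#' @param bootstrap_B bootstrap resamples for the stability check (0 to
#'   skip).
#' @param out_dir if not `NULL`, [write_report_bundle()] target.
#' @return list with all intermediate artifacts (`sim`, `cohort`,
#'   `attrition`, `indicators`, `imputation`, `screen`, `split`, `fit`,
#'   `selection`, `holdout`, `bootstrap`, `assignment`, `profiles`,
#'   `regression`, `top_ed`, `top_hospital`).
#' @export
run_pipeline <- function(n_patients = 2000L, n_distractors = 0L, seed = 1L,
                         spec = default_class_spec(), Kmax = 10L,
                         restarts = 5L, split_ratio = 0.7,
                         bootstrap_B = 0L, out_dir = NULL) {
  cfg <- simulation_config(n_patients = n_patients,
                           n_distractors = n_distractors, seed = seed)
  sim <- simulate_claims(spec, cfg, seed = seed)
  codes <- cfg$codes

  cohort <- build_cohort(sim$tables, codes)
  ind <- build_indicator_matrix(cohort$members, sim$tables, codes)

  imp <- impute_indicators(ind, max_iter = 10L, seed = derive_seed(seed, 41L))
  completed <- imp$completed

  scr <- correlation_screen(completed)
  lca_cols <- scr$kept
  lca_data <- completed[, lca_cols, drop = FALSE]

  sp <- split_sample(nrow(lca_data), ratio = split_ratio,
                     seed = derive_seed(seed, 42L))
  fit <- fit_grid(lca_data[sp$train, , drop = FALSE], Kmax = Kmax,
                  restarts = restarts, seed = derive_seed(seed, 43L))
  sel <- select_model(fit)

  holdout <- NULL; boot <- NULL; profiles <- NULL; regression <- NULL
  assignment <- NULL; top_ed <- NULL; top_hosp <- NULL
  if (!sel$failed) {
    chosen <- fit$models[[sel$chosen_k]]
    holdout <- holdout_confirmation(chosen, lca_data[sp$validation, , drop = FALSE],
                                    seed = derive_seed(seed, 44L))
    if (bootstrap_B > 0L) {
      boot <- bootstrap_stability(lca_data[sp$train, , drop = FALSE], chosen,
                                  B = bootstrap_B,
                                  seed = derive_seed(seed, 45L))
    }
    post <- lca_posterior(chosen, lca_data)
    assignment <- data.frame(patient_id = completed$patient_id,
                             class = post$map, stringsAsFactors = FALSE)
    out <- sim$outcomes[match(assignment$patient_id, sim$outcomes$patient_id), ,
                        drop = FALSE]
    profiles <- class_profiles(post$map, completed, outcomes = out,
                               charlson_cat = completed$charlson_cat)
    excl <- site_outlier_filter(sim$tables$ed_visits)
    top_ed <- top_diagnoses(sim$tables, assignment, source = "ed",
                            exclude_sites = excl)
    top_hosp <- top_diagnoses(sim$tables, assignment, source = "main_hospital")
    regression <- rbind(
      cbind(outcome = "admitted",
            logistic_or(out$admitted, post$map)),
      cbind(outcome = "admitted",
            logistic_or(out$admitted, post$map, age_cat = completed$age_cat)),
      cbind(outcome = "recurrent_ed",
            logistic_or(out$recurrent_ed, post$map)),
      cbind(outcome = "recurrent_ed",
            logistic_or(out$recurrent_ed, post$map,
                        age_cat = completed$age_cat)))
  }

  results <- list(seed = seed, n_patients = n_patients, sim = sim,
                  cohort = cohort$members, attrition = cohort$attrition,
                  indicators = ind, imputation = imp, screen = scr,
                  split = sp, fit = fit, selection = sel, holdout = holdout,
                  bootstrap = boot, assignment = assignment,
                  profiles = profiles, regression = regression,
                  top_ed = top_ed, top_hospital = top_hosp)
  if (!is.null(out_dir)) write_report_bundle(results, out_dir)
  results
}
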