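# Synthetic claims generator.  Two layers: a fast profile layer that samples
# indicator matrices directly from a latent class specification, and a full
# claims layer that emits raw event tables whose indicator reconstruction
# round-trips exactly to the input profiles.  Distractor patients exercise
# every rejection path of the cohort validation.

#' Latent class specification for the generator
#'
#' Houses the mixture weights, the class-conditional category distributions
#' of every indicator, the class-dependent outcome log-odds, and optional
#' planted local-independence violations (one indicator generated as a
#' noisy copy of another).
#'
#' @param class_weights probability vector over the K latent classes.
#' @param item_response named list over indicator columns; each element a
#'   `K x C_j` matrix of category probabilities (rows = classes, columns in
#'   the order of [indicator_levels()]).
#' @param outcome_log_odds named list with elements `recurrent_ed` and
#'   `admitted`, each `list(intercept =, offsets =)` with one log-odds
#'   offset per class (reference class offset 0).
#' @param copy_indicators named list of planted dependencies:
#'   `list(target = list(source =, prob =))` replaces the target indicator
#'   by the source's value with the given probability, violating local
#'   independence on purpose.
#' @return object of class `latent_class_spec`.
#' @export
latent_class_spec <- function(class_weights, item_response,
                              outcome_log_odds = NULL,
                              copy_indicators = list()) {
  spec <- list(n_classes = length(class_weights),
               class_weights = class_weights,
               item_response = item_response,
               outcome_log_odds = outcome_log_odds,
               copy_indicators = copy_indicators)
  class(spec) <- "latent_class_spec"
  validate_class_spec(spec)
}

validate_class_spec <- function(spec) {
  w <- spec$class_weights
  if (abs(sum(w) - 1) > 1e-12 || any(w < 0) || any(w > 1)) {
    stop("class_weights must be a probability vector summing to 1")
  }
  lv <- indicator_levels()
  for (nm in names(spec$item_response)) {
    th <- spec$item_response[[nm]]
    if (!is.matrix(th) || nrow(th) != spec$n_classes) {
      stop(sprintf("item_response[['%s']] must be a K x C matrix", nm))
    }
    if (!is.null(lv[[nm]]) && ncol(th) != length(lv[[nm]])) {
      stop(sprintf("item_response[['%s']] has %d columns, expected %d",
                   nm, ncol(th), length(lv[[nm]])))
    }
    if (any(th < 0) || any(th > 1) || any(abs(rowSums(th) - 1) > 1e-12)) {
      stop(sprintf("item_response[['%s']] rows must be probability vectors", nm))
    }
  }
  for (tgt in names(spec$copy_indicators)) {
    src <- spec$copy_indicators[[tgt]]$source
    if (!src %in% names(spec$item_response)) {
      stop("copy_indicators source not found: ", src)
    }
  }
  invisible(spec)
}

#' Default three-class generator specification
#'
#' Three classes along a disease-stage-by-utilisation gradient: class 1
#' "early disease stage and high utilisation", class 2 "progressing disease
#' stage and low utilisation" and class 3 "progressed disease stage and high
#' utilisation", with shares (0.365, 0.261, 0.374).  The class-conditional
#' category distributions are plausible presets patterned on that narrative,
#' chosen to be well separated so that parameter-recovery and selection
#' properties are testable; they are not ground truth for any real cohort.
#' Creatinine measurement is generated as a noisy copy of the HbA1c
#' indicator (copy probability 0.45, implying an overall correlation of
#' about 0.63 once the shared class structure is accounted for), planting
#' the local-independence violation that the correlation screen is meant to
#' find.  Outcome log-odds target large-sample admission odds ratios of
#' 1.27 (class 2 vs 1) and 1.38 (class 3 vs 1), and 1.03 / 1.17 for
#' recurrent ED visits.
#'
#' @return a `latent_class_spec`.
#' @export
default_class_spec <- function() {
  ir <- list(
    sex = rbind(c(0.46, 0.54),
                c(0.51, 0.49),
                c(0.55, 0.45)),
    age_cat = rbind(c(0.095, 0.243, 0.513, 0.149),
                    c(0.218, 0.291, 0.336, 0.155),
                    c(0.064, 0.278, 0.566, 0.092)),
    complication_cat = rbind(c(0.975, 0.024, 0.001),
                             c(0.920, 0.076, 0.004),
                             c(0.008, 0.610, 0.382)),
    medication_cat = rbind(c(0.945, 0.048, 0.004, 0.003),
                           c(0.025, 0.105, 0.410, 0.460),
                           c(0.035, 0.165, 0.380, 0.420)),
    gp_cat = rbind(c(0.004, 0.026, 0.970),
                   c(0.130, 0.300, 0.570),
                   c(0.004, 0.021, 0.975)),
    genspec_cat = rbind(c(0.015, 0.105, 0.880),
                        c(0.880, 0.105, 0.015),
                        c(0.030, 0.140, 0.830)),
    specspec_cat = rbind(c(0.36, 0.48, 0.16),
                         c(0.72, 0.25, 0.03),
                         c(0.08, 0.40, 0.52)),
    hba1c_cat = rbind(c(0.040, 0.320, 0.640),
                      c(0.470, 0.370, 0.160),
                      c(0.025, 0.215, 0.760)),
    microalb_cat = rbind(c(0.900, 0.095, 0.005),
                         c(0.960, 0.038, 0.002),
                         c(0.480, 0.430, 0.090)),
    creatinine_cat = rbind(c(0.040, 0.320, 0.640),
                           c(0.470, 0.370, 0.160),
                           c(0.025, 0.215, 0.760)),
    fundus_cat = rbind(c(0.520, 0.450, 0.030),
                       c(0.960, 0.038, 0.002),
                       c(0.450, 0.510, 0.040)))
  latent_class_spec(
    class_weights = c(0.365, 0.261, 0.374),
    item_response = ir,
    outcome_log_odds = list(
      admitted = list(intercept = stats::qlogis(0.608),
                      offsets = c(0, log(1.27), log(1.38))),
      recurrent_ed = list(intercept = stats::qlogis(0.227),
                          offsets = c(0, log(1.03), log(1.17)))),
    copy_indicators = list(
      creatinine_cat = list(source = "hba1c_cat", prob = 0.45)))
}

#' Simulation configuration for the claims layer
#'
#' @param n_patients number of cohort patients to synthesise.
#' @param n_distractors number of patients that must fail cohort
#'   validation, split evenly over three archetypes: type-1-diabetes-only,
#'   single-quarter DM coders, and patients with no DM code at all.
#' @param missing_prescription_region_share fraction of patients whose SHI
#'   region does not transmit prescription data (applied by
#'   [inject_missing_prescriptions()]).
#' @param calendar_range first and last calendar quarter of the claims
#'   history; must span at least 9 quarters (8 lookback plus index).
#' @param codes a [code_config()].
#' @param seed integer master seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 1000L,
                              n_distractors = 0L,
                              missing_prescription_region_share = 0.204,
                              calendar_range = c("2014Q1", "2016Q4"),
                              codes = code_config(),
                              seed = 1L) {
  stopifnot(n_patients > 0, n_distractors >= 0,
            missing_prescription_region_share >= 0,
            missing_prescription_region_share <= 1)
  span <- quarter_index(calendar_range[2]) - quarter_index(calendar_range[1]) + 1L
  if (span < 9L) stop("calendar_range must span at least 9 quarters")
  structure(list(n_patients = as.integer(n_patients),
                 n_distractors = as.integer(n_distractors),
                 missing_prescription_region_share = missing_prescription_region_share,
                 calendar_range = calendar_range,
                 codes = codes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# one categorical draw per row from a K x C matrix of class-conditional
# probabilities, vectorised over patients
draw_categories <- function(theta, labels, values) {
  p <- theta[labels, , drop = FALSE]
  u <- stats::runif(length(labels))
  cum <- t(apply(p, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  values[pmin(idx, length(values))]
}

#' Sample indicator profiles from a latent class specification
#'
#' Draws each patient's class from the mixture weights and each indicator
#' from its class-conditional category distribution; planted copy
#' dependencies are applied afterwards.  The true labels are returned for
#' recovery tests.
#'
#' @param spec a [latent_class_spec()].
#' @param n number of patients.
#' @param seed integer seed.
#' @return list with `profiles` (data frame of indicator columns) and
#'   `labels` (integer class per patient).
#' @export
sample_indicator_profiles <- function(spec, n, seed = 1L) {
  validate_class_spec(spec)
  stopifnot(n > 0)
  set.seed(seed)
  lv <- indicator_levels()
  labels <- sample.int(spec$n_classes, n, replace = TRUE,
                       prob = spec$class_weights)
  profiles <- list()
  for (nm in names(spec$item_response)) {
    profiles[[nm]] <- draw_categories(spec$item_response[[nm]], labels,
                                      if (is.null(lv[[nm]])) seq_len(ncol(spec$item_response[[nm]])) else lv[[nm]])
  }
  profiles <- as.data.frame(profiles)
  for (tgt in names(spec$copy_indicators)) {
    cp <- spec$copy_indicators[[tgt]]
    take <- stats::runif(n) < cp$prob
    profiles[[tgt]][take] <- profiles[[cp$source]][take]
  }
  assert_indicator_matrix(profiles, allow_missing = FALSE)
  list(profiles = profiles, labels = labels)
}

#' Generate dichotomous outcomes from class-specific logits
#'
#' Recurrent ED visits (more than one visit in 2016) and inpatient
#' admission (at least one admission) are drawn as Bernoulli variables from
#' `plogis(intercept + offset[class])`.
#'
#' @param labels integer class labels.
#' @param spec a [latent_class_spec()] with `outcome_log_odds` set.
#' @param seed integer seed.
#' @return data frame with logical columns `recurrent_ed` and `admitted`.
#' @export
generate_outcomes <- function(labels, spec, seed = 1L) {
  olo <- spec$outcome_log_odds
  if (is.null(olo)) stop("spec has no outcome_log_odds")
  for (nm in names(olo)) {
    if (length(olo[[nm]]$offsets) < max(labels)) {
      stop("outcome_log_odds offsets not defined for all classes")
    }
  }
  set.seed(seed)
  out <- lapply(olo, function(o) {
    p <- stats::plogis(o$intercept + o$offsets[labels])
    stats::rbinom(length(labels), 1L, p) == 1L
  })
  as.data.frame(out)[, c("recurrent_ed", "admitted"), drop = FALSE]
}

# sample k distinct quarters out of a window (character labels)
pick_quarters <- function(window, k) {
  window[sample.int(length(window), k)]
}

# uniform random dates within a quarter label
random_date_in_quarter <- function(quarter) {
  i <- quarter_index(quarter)
  start <- as.Date(sprintf("%d-%02d-01", i %/% 4L, (i %% 4L) * 3L + 1L))
  stop_ <- seq(start, by = "3 months", length.out = 2L)[2L] - 1L
  start + sample.int(as.integer(stop_ - start) + 1L, length(quarter), replace = TRUE) - 1L
}

ED_CODE_POOL <- c("I10", "M54", "S00", "I63", "R10", "J18", "I50", "R07", "I48")
HOSP_CODE_POOL <- c("I63", "I50", "S06", "I21", "A41", "J18", "G45", "N17", "J44")
COMORBIDITY_POOL <- c("I10", "I50", "I48", "J44", "M54", "N18", "I25")

#' Synthesise claims tables from indicator profiles
#'
#' Constrained inverse of the indicator construction: emits raw event
#' tables such that [build_indicator_matrix()] applied to the output
#' reproduces the input profiles cell for cell.  Event placements
#' consistent with each category (which quarters carry a code, how many
#' quarters out of the permitted range) are chosen uniformly.  Cohort
#' members always carry confirmed type-2 codes in two distinct lookback
#' quarters, so they pass validation condition 1; distractor patients
#' (three archetypes) fail validation or are allocated away from T2DM.
#'
#' @param profiles indicator data frame from [sample_indicator_profiles()].
#' @param labels integer class labels (used for class-flavoured ED and
#'   hospital diagnosis pools).
#' @param config a [simulation_config()].
#' @param outcomes optional outcome table from [generate_outcomes()];
#'   defaults to no recurrent visits and no admissions.
#' @return a list of class `claims_tables` with elements `patients`,
#'   `outpatient_diagnoses`, `billing_events`, `prescriptions`,
#'   `ed_visits`, `dmp`; patient roles are attached as attribute `truth`.
#' @export
synthesize_claims <- function(profiles, labels, config, outcomes = NULL) {
  assert_indicator_matrix(profiles, allow_missing = FALSE)
  n <- nrow(profiles)
  stopifnot(length(labels) == n)
  if (is.null(outcomes)) {
    outcomes <- data.frame(recurrent_ed = rep(FALSE, n), admitted = rep(FALSE, n))
  }
  stopifnot(nrow(outcomes) == n)
  codes <- config$codes
  set.seed(derive_seed(config$seed, 11L))

  ids <- sprintf("P%06d", seq_len(n))
  index_q <- sample.int(4L, n, replace = TRUE)
  index_quarter <- quarter_label(2016L, index_q)

  age_rng <- list(c(20L, 55L), c(56L, 70L), c(71L, 85L), c(86L, 95L))
  age <- vapply(profiles$age_cat, function(a) {
    r <- age_rng[[a]]; r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
  }, integer(1))

  patients <- data.frame(
    patient_id = ids,
    sex = profiles$sex,
    birth_year = 2016L - age,
    region_id = sample.int(8L, n, replace = TRUE),
    insurance_status = sample(c("member", "family", "retiree"), n,
                              replace = TRUE, prob = c(0.23, 0.03, 0.74)),
    rx_transmitted = TRUE,
    stringsAsFactors = FALSE)

  dx <- list(); bill <- list(); rx <- list(); visits <- list(); dmp <- list()
  group_digits <- list(metabolic = c("0", "1"), kidney = "2", eye = "3",
                       neuro_vascular = c("4", "5"), multiple = "7")
  lab_cols <- c(hba1c_cat = codes$hba1c_codes[1],
                microalb_cat = codes$microalbuminuria_codes[1],
                creatinine_cat = codes$creatinine_codes[1],
                fundus_cat = codes$fundus_codes[1])
  spec_cols <- c(gp_cat = "GP", genspec_cat = "general_specialist",
                 specspec_cat = "specialised_specialist")

  ed_extra_prob <- c(0.05, 0.25, 0.30)  # chance of an E11 ED code per class
  hosp_e11_prob <- c(0.03, 0.20, 0.25)

  for (i in seq_len(n)) {
    lb4 <- lookback_quarters(index_quarter[i], 4L)
    # confirmed T2DM stem codes in two distinct quarters: validation cond. 1
    base_q <- pick_quarters(lb4, 2L)
    dx[[length(dx) + 1L]] <- data.frame(
      patient_id = ids[i], quarter = base_q, icd_code = "E11.9",
      qualifier = sample(c("confirmed", "condition_after"), 2L,
                         replace = TRUE, prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE)
    # complication-group codes via the fourth digit
    cc <- profiles$complication_cat[i]
    if (cc > 0L) {
      ngr <- if (cc == 1L) sample(1:2, 1L) else sample(3:5, 1L)
      grs <- sample(names(group_digits), ngr)
      digs <- vapply(grs, function(g) sample(group_digits[[g]], 1L), character(1))
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = ids[i], quarter = sample(lb4, ngr, replace = TRUE),
        icd_code = paste0("E11.", digs), qualifier = "confirmed",
        stringsAsFactors = FALSE)
    }
    # a little comorbidity background noise (non-DM codes)
    ncom <- sample(0:2, 1L)
    if (ncom > 0L) {
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = ids[i], quarter = sample(lb4, ncom, replace = TRUE),
        icd_code = sample(COMORBIDITY_POOL, ncom), qualifier = "confirmed",
        stringsAsFactors = FALSE)
    }
    # occasionally a suspected code, ignored by the qualifier filter
    if (stats::runif(1) < 0.1) {
      dx[[length(dx) + 1L]] <- data.frame(
        patient_id = ids[i], quarter = sample(lb4, 1L), icd_code = "E11.9",
        qualifier = "suspected", stringsAsFactors = FALSE)
    }
    # physician-contact billing events by specialty group
    for (cl in names(spec_cols)) {
      cat_ <- profiles[[cl]][i]
      if (cat_ > 0L) {
        k <- if (cat_ == 1L) sample(1:2, 1L) else sample(3:4, 1L)
        bill[[length(bill) + 1L]] <- data.frame(
          patient_id = ids[i], quarter = pick_quarters(lb4, k),
          billing_code = "GOP-CONS", specialty_group = spec_cols[[cl]],
          stringsAsFactors = FALSE)
      }
    }
    # process-quality billing codes, claimed under specialty "other"
    for (cl in names(lab_cols)) {
      cat_ <- profiles[[cl]][i]
      if (cat_ > 0L) {
        k <- if (cat_ == 1L) sample(1:2, 1L) else sample(3:4, 1L)
        qs <- pick_quarters(lb4, k)
        if (stats::runif(1) < 0.15) qs <- c(qs, qs[1])  # same-quarter repeat
        bill[[length(bill) + 1L]] <- data.frame(
          patient_id = ids[i], quarter = qs, billing_code = lab_cols[[cl]],
          specialty_group = "other", stringsAsFactors = FALSE)
      }
    }
    # prescriptions by medication category
    med <- profiles$medication_cat[i]
    if (med %in% c(1L, 3L)) {
      k <- sample(1:3, 1L)
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = ids[i], quarter = sample(lb4, k, replace = TRUE),
        atc_code = paste0(codes$oad_atc_prefix, "A02"), stringsAsFactors = FALSE)
    }
    if (med %in% c(2L, 3L)) {
      k <- sample(1:3, 1L)
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = ids[i], quarter = sample(lb4, k, replace = TRUE),
        atc_code = paste0(codes$insulin_atc_prefix, "B01"), stringsAsFactors = FALSE)
    }
    # ED visits: index visit first, recurrent visits after it
    idate <- random_date_in_quarter(index_quarter[i])
    ncode <- sample(1:3, 1L)
    ecodes <- sample(ED_CODE_POOL, ncode)
    if (stats::runif(1) < ed_extra_prob[labels[i]]) ecodes <- c("E11", ecodes)
    main_icd <- NA_character_
    if (outcomes$admitted[i]) {
      main_icd <- if (stats::runif(1) < hosp_e11_prob[labels[i]]) "E11.9" else
        sample(HOSP_CODE_POOL, 1L)
    }
    visits[[length(visits) + 1L]] <- data.frame(
      patient_id = ids[i], visit_date = idate, site_id = sample.int(13L, 1L),
      ed_icd_codes = paste(ecodes, collapse = ";"),
      admitted = outcomes$admitted[i], main_hospital_icd = main_icd,
      stringsAsFactors = FALSE)
    if (outcomes$recurrent_ed[i]) {
      nex <- sample(1:2, 1L)
      span <- as.integer(as.Date("2016-12-31") - idate)
      edates <- idate + sample.int(span + 1L, nex, replace = TRUE) - 1L
      visits[[length(visits) + 1L]] <- data.frame(
        patient_id = ids[i], visit_date = edates,
        site_id = sample.int(13L, nex, replace = TRUE),
        ed_icd_codes = vapply(seq_len(nex), function(z)
          paste(sample(ED_CODE_POOL, sample(1:3, 1L)), collapse = ";"),
          character(1)),
        admitted = FALSE, main_hospital_icd = NA_character_,
        stringsAsFactors = FALSE)
    }
    # some T2DM patients appear in the disease management programme
    if (stats::runif(1) < 0.3) {
      dmp[[length(dmp) + 1L]] <- data.frame(
        patient_id = ids[i], programme = "T2DMP", quarter = sample(lb4, 1L),
        stringsAsFactors = FALSE)
    }
  }

  truth <- data.frame(patient_id = ids, role = "cohort", class = labels,
                      stringsAsFactors = FALSE)

  # ---- distractors ------------------------------------------------------
  nd <- config$n_distractors
  if (nd > 0L) {
    arch <- rep(c("t1dm_only", "single_quarter", "no_dm"), length.out = nd)
    did <- sprintf("D%05d", seq_len(nd))
    for (i in seq_len(nd)) {
      iq <- quarter_label(2016L, sample.int(4L, 1L))
      lb4 <- lookback_quarters(iq, 4L)
      lb8 <- lookback_quarters(iq, 8L)
      patients <- rbind(patients, data.frame(
        patient_id = did[i], sex = sample(1:2, 1L),
        birth_year = 2016L - sample(25:90, 1L),
        region_id = sample.int(8L, 1L),
        insurance_status = "member", rx_transmitted = TRUE,
        stringsAsFactors = FALSE))
      adm <- stats::runif(1) < 0.4
      visits[[length(visits) + 1L]] <- data.frame(
        patient_id = did[i], visit_date = random_date_in_quarter(iq),
        site_id = sample.int(13L, 1L),
        ed_icd_codes = paste(sample(ED_CODE_POOL, 2L), collapse = ";"),
        admitted = adm,
        main_hospital_icd = if (adm) sample(HOSP_CODE_POOL, 1L) else NA_character_,
        stringsAsFactors = FALSE)
      bill[[length(bill) + 1L]] <- data.frame(
        patient_id = did[i], quarter = sample(lb4, 1L),
        billing_code = "GOP-CONS", specialty_group = "GP",
        stringsAsFactors = FALSE)
      if (arch[i] == "t1dm_only") {
        dx[[length(dx) + 1L]] <- data.frame(
          patient_id = did[i], quarter = pick_quarters(lb8, 3L),
          icd_code = "E10.9", qualifier = "confirmed", stringsAsFactors = FALSE)
        rx[[length(rx) + 1L]] <- data.frame(
          patient_id = did[i], quarter = sample(lb4, 2L, replace = TRUE),
          atc_code = paste0(codes$insulin_atc_prefix, "B01"),
          stringsAsFactors = FALSE)
        dmp[[length(dmp) + 1L]] <- data.frame(
          patient_id = did[i], programme = "T1DMP", quarter = sample(lb4, 1L),
          stringsAsFactors = FALSE)
      } else if (arch[i] == "single_quarter") {
        dx[[length(dx) + 1L]] <- data.frame(
          patient_id = did[i], quarter = sample(lb4, 1L), icd_code = "E11.9",
          qualifier = "confirmed", stringsAsFactors = FALSE)
      } else {  # no_dm: non-diabetic outpatient history only
        dx[[length(dx) + 1L]] <- data.frame(
          patient_id = did[i], quarter = sample(lb4, 2L, replace = TRUE),
          icd_code = "I10", qualifier = "confirmed", stringsAsFactors = FALSE)
      }
    }
    truth <- rbind(truth, data.frame(patient_id = did,
                                     role = paste0("distractor_", arch),
                                     class = NA_integer_,
                                     stringsAsFactors = FALSE))
  }

  tables <- list(patients = patients,
                 outpatient_diagnoses = do.call(rbind, dx),
                 billing_events = do.call(rbind, bill),
                 prescriptions = if (length(rx)) do.call(rbind, rx) else
                   data.frame(patient_id = character(), quarter = character(),
                              atc_code = character(), stringsAsFactors = FALSE),
                 ed_visits = do.call(rbind, visits),
                 dmp = if (length(dmp)) do.call(rbind, dmp) else
                   data.frame(patient_id = character(), programme = character(),
                              quarter = character(), stringsAsFactors = FALSE))
  rownames(tables$patients) <- NULL
  for (nm in names(tables)) rownames(tables[[nm]]) <- NULL
  class(tables) <- "claims_tables"
  attr(tables, "truth") <- truth
  attr(tables, "calendar_range") <- config$calendar_range
  tables
}

#' Remove prescription data for a non-transmitting region
#'
#' Emulates an association of SHI physicians that does not transmit drug
#' prescription data: roughly `share` of patients are reassigned to a
#' dedicated region, all their prescription rows are removed and they are
#' flagged (`rx_transmitted = FALSE`) so that the medication indicator is
#' treated as missing rather than "no medication".
#'
#' @param tables a `claims_tables` list.
#' @param share fraction of patients affected, in `[0, 1]`.
#' @param seed integer seed.
#' @return modified `claims_tables`.
#' @export
inject_missing_prescriptions <- function(tables, share, seed = 1L) {
  stopifnot(share >= 0, share <= 1)
  if (share == 0) return(tables)
  set.seed(derive_seed(seed, 29L))
  n <- nrow(tables$patients)
  hit <- stats::runif(n) < share
  if (share >= 1) hit <- rep(TRUE, n)
  region <- max(tables$patients$region_id) + 1L
  tables$patients$region_id[hit] <- region
  tables$patients$rx_transmitted[hit] <- FALSE
  drop_ids <- tables$patients$patient_id[hit]
  tables$prescriptions <-
    tables$prescriptions[!(tables$prescriptions$patient_id %in% drop_ids), ,
                         drop = FALSE]
  rownames(tables$prescriptions) <- NULL
  attr(tables, "non_transmitting_region") <- region
  tables
}

#' One-call synthetic study generator
#'
#' Samples profiles, outcomes and full claims tables from a specification,
#' then removes prescriptions for the non-transmitting region.
#'
#' @param spec a [latent_class_spec()]; defaults to [default_class_spec()].
#' @param config a [simulation_config()].
#' @param seed master seed; overrides `config$seed`.
#' @return list with `tables`, `profiles`, `labels`, `outcomes`, `truth`.
#' @export
simulate_claims <- function(spec = default_class_spec(),
                            config = simulation_config(),
                            seed = config$seed) {
  config$seed <- as.integer(seed)
  pr <- sample_indicator_profiles(spec, config$n_patients,
                                  seed = derive_seed(seed, 1L))
  out <- generate_outcomes(pr$labels, spec, seed = derive_seed(seed, 2L))
  tables <- synthesize_claims(pr$profiles, pr$labels, config, outcomes = out)
  tables <- inject_missing_prescriptions(
    tables, config$missing_prescription_region_share,
    seed = derive_seed(seed, 3L))
  out$patient_id <- sprintf("P%06d", seq_len(config$n_patients))
  list(tables = tables, profiles = pr$profiles, labels = pr$labels,
       outcomes = out[, c("patient_id", "recurrent_ed", "admitted")],
       truth = attr(tables, "truth"))
}
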