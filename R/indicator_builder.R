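# Construction of the per-patient categorical indicator matrix: disease
# stage (complication groups, medication), quarter-based physician contact
# counts by specialty, process-quality measurements, plus the Charlson
# comorbidity index and demographic variables.

#' Count lookback quarters containing a matching event
#'
#' Counts the distinct calendar quarters of the window in which the patient
#' has at least one matching event.  Billing flat rates are claimed per
#' quarter, so the quarter count is the natural contact measure; two events
#' in the same quarter count once.
#'
#' @param event_quarters character vector of quarter labels of the
#'   patient's matching events (any number of rows).
#' @param window quarter labels from [lookback_quarters()].
#' @return list with `count` (0--4) and `category` (0, 1, 2).
#' @export
quarters_with_event <- function(event_quarters, window) {
  cnt <- length(intersect(unique(event_quarters), window))
  list(count = cnt, category = categorise_quarters(cnt))
}

#' Count documented DM complication groups
#'
#' Complication groups (metabolic, eye, kidney, neuro-vascular, multiple)
#' are identified from the fourth digit of E10--E14 codes with a valid
#' qualifier in the one-year window; the distinct-group count is
#' categorised as 0 / 1--2 / >= 3.
#'
#' @param icd_codes,qualifiers,quarters parallel vectors of the patient's
#'   outpatient diagnosis rows.
#' @param window quarter labels of the one-year lookback.
#' @param codes a [code_config()].
#' @return list with `groups` (character vector) and `category`.
#' @export
complication_group_count <- function(icd_codes, qualifiers, quarters, window,
                                     codes = code_config()) {
  keep <- qualifiers %in% VALID_QUALIFIERS & quarters %in% window
  code <- normalise_icd(icd_codes[keep])
  dm <- code[matches_any_prefix(code, codes$dm_icd_prefixes)]
  digit <- substr(dm, 4L, 4L)
  groups <- unique(stats::na.omit(codes$complication_group_map[digit]))
  list(groups = groups, category = categorise_complications(length(groups)))
}

#' Charlson comorbidity index from outpatient diagnoses
#'
#' Sums the weights of distinct comorbid condition groups matched by ICD
#' prefix (default mapping: [charlson_quan_icd10()]).  Hierarchy rules keep
#' only the more severe member of the diabetes, liver-disease and
#' malignancy pairs.  Score categories follow the reporting convention
#' 0 / 1--2 / 3--4 / >= 5.
#'
#' @param icd_codes,qualifiers,quarters the patient's outpatient diagnosis
#'   rows; only valid qualifiers inside the window count.
#' @param window quarter labels of the lookback window.
#' @param codes a [code_config()].
#' @return list with `score`, `conditions` and `category` (one of
#'   `"0"`, `"1-2"`, `"3-4"`, `">=5"`).
#' @export
charlson_score <- function(icd_codes, qualifiers, quarters, window,
                           codes = code_config()) {
  keep <- qualifiers %in% VALID_QUALIFIERS & quarters %in% window
  code <- unique(normalise_icd(icd_codes[keep]))
  map <- codes$charlson_map
  hit <- vapply(seq_len(nrow(map)), function(i) {
    any(matches_any_prefix(code, strsplit(map$prefixes[i], ",", fixed = TRUE)[[1]]))
  }, logical(1))
  conds <- map$condition[hit]
  # hierarchy: severe member supersedes the mild one
  for (pair in list(c("diabetes_complicated", "diabetes_uncomplicated"),
                    c("moderate_severe_liver", "mild_liver"),
                    c("metastatic_solid_tumour", "any_malignancy"))) {
    if (all(pair %in% conds)) conds <- setdiff(conds, pair[2])
  }
  score <- sum(map$weight[match(conds, map$condition)])
  category <- cut(score, c(-Inf, 0, 2, 4, Inf),
                  labels = c("0", "1-2", "3-4", ">=5"))
  list(score = score, conditions = conds, category = as.character(category))
}

#' Age category and sex at the index year
#'
#' Age at each 2016 visit is visit year minus birth year (claims carry no
#' birth dates); with multiple visits the mean is taken and rounded half
#' up before categorisation, so a mean of 70.5 falls into the 71--85
#' category.
#'
#' @param birth_year the patient's birth year.
#' @param visit_dates dates of the patient's 2016 ED visits.
#' @param sex sex code (1 male, 2 female), passed through.
#' @return list with `age` (rounded mean), `age_cat` and `sex`.
#' @export
age_and_sex <- function(birth_year, visit_dates, sex) {
  yrs <- as.integer(format(as.Date(visit_dates), "%Y"))
  stopifnot(length(yrs) >= 1L)
  age <- round_half_up(mean(yrs - birth_year))
  list(age = age, age_cat = categorise_age(age), sex = as.integer(sex))
}

# distinct (patient, quarter) counts for rows matching a selector, within
# each patient's lookback window; returns named integer vector
count_quarters_by_patient <- function(patient_id, quarter, idx_of, lookback) {
  qidx <- quarter_index(quarter)
  iq <- idx_of[patient_id]
  inwin <- !is.na(iq) & qidx >= iq - lookback & qidx <= iq - 1L
  if (!any(inwin)) return(integer(0))
  uq <- unique(data.frame(patient_id = patient_id[inwin],
                          qidx = qidx[inwin], stringsAsFactors = FALSE))
  tab <- table(uq$patient_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Assemble the indicator matrix for a cohort
#'
#' Builds all eleven categorical indicators over the one-year (four
#' quarter) lookback before each patient's index quarter, plus the
#' Charlson score.  Events absent while the patient is present at least
#' once in the outpatient data are coded as category 0; patients with no
#' outpatient rows at all get missing utilisation indicators.  The
#' medication indicator is missing (not 0) for patients of a
#' non-transmitting prescription region.
#'
#' @param cohort cohort member data frame from [build_cohort()].
#' @param tables a `claims_tables` list.
#' @param codes a [code_config()].
#' @return data frame with `patient_id`, the indicator columns of
#'   [indicator_columns()], `charlson_score` and `charlson_cat`.
#' @export
build_indicator_matrix <- function(cohort, tables, codes = code_config()) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  ids <- cohort$patient_id
  n <- length(ids)
  idx_of <- stats::setNames(quarter_index(cohort$index_quarter), ids)

  pat <- tables$patients[match(ids, tables$patients$patient_id), , drop = FALSE]
  vs <- tables$ed_visits[tables$ed_visits$patient_id %in% ids, , drop = FALSE]

  # demographic indicators
  ages <- as.integer(format(as.Date(vs$visit_date), "%Y")) -
    pat$birth_year[match(vs$patient_id, ids)]
  mean_age <- tapply(ages, vs$patient_id, mean)
  age <- round_half_up(as.numeric(mean_age[ids]))

  out <- data.frame(patient_id = ids,
                    sex = as.integer(pat$sex),
                    age_cat = categorise_age(age),
                    stringsAsFactors = FALSE)

  # outpatient presence (anywhere in the data, not only the window)
  present <- ids %in% tables$outpatient_diagnoses$patient_id |
    ids %in% tables$billing_events$patient_id

  # complication groups and Charlson over the one-year window
  dx <- tables$outpatient_diagnoses
  dx <- dx[dx$patient_id %in% ids & dx$qualifier %in% VALID_QUALIFIERS, ,
           drop = FALSE]
  dq <- quarter_index(dx$quarter)
  iq <- idx_of[dx$patient_id]
  dx_win <- dx[!is.na(iq) & dq >= iq - 4L & dq <= iq - 1L, , drop = FALSE]

  code <- normalise_icd(dx_win$icd_code)
  dm_rows <- matches_any_prefix(code, codes$dm_icd_prefixes)
  grp <- codes$complication_group_map[substr(code, 4L, 4L)]
  grp[!dm_rows] <- NA
  has_grp <- !is.na(grp)
  ngroups <- rep(0L, n)
  if (any(has_grp)) {
    ug <- unique(data.frame(patient_id = dx_win$patient_id[has_grp],
                            grp = grp[has_grp], stringsAsFactors = FALSE))
    tab <- table(ug$patient_id)
    m <- match(ids, names(tab))
    ngroups <- ifelse(is.na(m), 0L, as.integer(tab)[m])
  }
  out$complication_cat <- ifelse(present, categorise_complications(ngroups), NA_integer_)

  # medication: missing for the non-transmitting region
  rx <- tables$prescriptions
  rx <- rx[rx$patient_id %in% ids, , drop = FALSE]
  rq <- quarter_index(rx$quarter)
  riq <- idx_of[rx$patient_id]
  rx_win <- rx[!is.na(riq) & rq >= riq - 4L & rq <= riq - 1L, , drop = FALSE]
  atc <- toupper(rx_win$atc_code)
  has_ins <- ids %in% rx_win$patient_id[startsWith(atc, codes$insulin_atc_prefix)]
  has_oad <- ids %in% rx_win$patient_id[startsWith(atc, codes$oad_atc_prefix)]
  med <- has_oad + 2L * has_ins  # 0 none, 1 OAD, 2 insulin, 3 both
  rx_ok <- if ("rx_transmitted" %in% names(pat)) pat$rx_transmitted else TRUE
  out$medication_cat <- ifelse(rx_ok & present, med, NA_integer_)

  # quarter-count indicators
  be <- tables$billing_events
  be <- be[be$patient_id %in% ids, , drop = FALSE]
  if (nrow(be) > 0) {
    known <- be$specialty_group %in% codes$specialty_groups
    if (any(!known)) {
      stop("unknown specialty_group label(s): ",
           paste(unique(be$specialty_group[!known]), collapse = ", "))
    }
  }
  count_col <- function(rows) {
    cnt <- count_quarters_by_patient(rows$patient_id, rows$quarter, idx_of, 4L)
    m <- match(ids, names(cnt))
    v <- ifelse(is.na(m), 0L, as.integer(cnt)[m])
    ifelse(present, categorise_quarters(v), NA_integer_)
  }
  out$gp_cat <- count_col(be[be$specialty_group == "GP", , drop = FALSE])
  out$genspec_cat <- count_col(be[be$specialty_group == "general_specialist", , drop = FALSE])
  out$specspec_cat <- count_col(be[be$specialty_group == "specialised_specialist", , drop = FALSE])
  out$hba1c_cat <- count_col(be[be$billing_code %in% codes$hba1c_codes, , drop = FALSE])
  out$microalb_cat <- count_col(be[be$billing_code %in% codes$microalbuminuria_codes, , drop = FALSE])
  out$creatinine_cat <- count_col(be[be$billing_code %in% codes$creatinine_codes, , drop = FALSE])
  out$fundus_cat <- count_col(be[be$billing_code %in% codes$fundus_codes, , drop = FALSE])

  # Charlson comorbidity index (same one-year window)
  map <- codes$charlson_map
  cond_w <- stats::setNames(map$weight, map$condition)
  cond_of_code <- function(cd) {
    for (i in seq_len(nrow(map))) {
      if (matches_any_prefix(cd, strsplit(map$prefixes[i], ",", fixed = TRUE)[[1]])) {
        return(map$condition[i])
      }
    }
    NA_character_
  }
  ucode <- unique(code)
  cond_lookup <- vapply(ucode, cond_of_code, character(1))
  row_cond <- cond_lookup[match(code, ucode)]
  has_cond <- !is.na(row_cond)
  score <- rep(0L, n)
  if (any(has_cond)) {
    uc <- unique(data.frame(patient_id = dx_win$patient_id[has_cond],
                            cond = row_cond[has_cond], stringsAsFactors = FALSE))
    score <- vapply(split(uc$cond, uc$patient_id), function(cs) {
      for (pair in list(c("diabetes_complicated", "diabetes_uncomplicated"),
                        c("moderate_severe_liver", "mild_liver"),
                        c("metastatic_solid_tumour", "any_malignancy"))) {
        if (all(pair %in% cs)) cs <- setdiff(cs, pair[2])
      }
      sum(cond_w[cs])
    }, numeric(1))[as.character(ids)]
    score[is.na(score)] <- 0L
  }
  out$charlson_score <- ifelse(present, as.integer(score), NA_integer_)
  out$charlson_cat <- as.character(cut(out$charlson_score, c(-Inf, 0, 2, 4, Inf),
                                       labels = c("0", "1-2", "3-4", ">=5")))

  assert_indicator_matrix(out, allow_missing = TRUE)
  rownames(out) <- NULL
  out
}
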