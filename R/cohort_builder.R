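# Cohort extraction and validation: (I) find patients with any diabetes
# code, (II) validate the diagnosis with four ordered conditions built
# around an M2Q-style repeated-coding criterion relaxed to an 8-quarter
# window, (III) allocate a diabetes type and keep T2DM patients with at
# least one documented outpatient case.

VALID_QUALIFIERS <- c("confirmed", "condition_after")

# earliest 2016 ED visit per patient; errors on visits outside 2016
index_visits <- function(tables) {
  v <- tables$ed_visits
  v$visit_date <- as.Date(v$visit_date)
  yr <- as.integer(format(v$visit_date, "%Y"))
  if (any(yr != 2016L)) {
    stop("ED visits outside 2016 found; the index year must be 2016")
  }
  ord <- order(v$patient_id, v$visit_date)
  v <- v[ord, , drop = FALSE]
  first <- !duplicated(v$patient_id)
  iv <- v[first, c("patient_id", "visit_date"), drop = FALSE]
  iv$index_quarter <- quarter_of_date(iv$visit_date)
  names(iv)[2] <- "index_date"
  rownames(iv) <- NULL
  iv
}

# per-patient diabetes evidence over the 8-quarter validation window
dm_evidence <- function(tables, codes) {
  iv <- index_visits(tables)
  iv$index_qidx <- quarter_index(iv$index_quarter)

  ev <- data.frame(patient_id = iv$patient_id,
                   index_date = iv$index_date,
                   index_quarter = iv$index_quarter,
                   stringsAsFactors = FALSE)
  zero <- rep(0L, nrow(ev)); f <- rep(FALSE, nrow(ev))
  ev$n_dm_quarters <- zero
  ev$has_ed_dm <- f; ev$has_hospital_dm <- f; ev$has_rx <- f
  ev$has_insulin <- f; ev$has_oad <- f
  ev$has_e10 <- f; ev$has_e11 <- f; ev$has_e12_14 <- f
  ev$t1dmp <- f; ev$t2dmp <- f
  ev$outpatient_present <- f

  idx_of <- stats::setNames(ev$index_qidx <- iv$index_qidx, ev$patient_id)
  e12_14 <- setdiff(codes$dm_icd_prefixes, c(codes$t1dm_prefix, codes$t2dm_prefix))

  flag <- function(ids) ev$patient_id %in% unique(ids)

  # outpatient diagnoses in the 8-quarter lookback with a valid qualifier
  dx <- tables$outpatient_diagnoses
  if (!is.null(dx) && nrow(dx) > 0) {
    ev$outpatient_present <- flag(dx$patient_id)
    dx <- dx[dx$qualifier %in% VALID_QUALIFIERS, , drop = FALSE]
    qidx <- quarter_index(dx$quarter)
    iq <- idx_of[dx$patient_id]
    inwin <- !is.na(iq) & qidx >= iq - 8L & qidx <= iq - 1L
    code <- normalise_icd(dx$icd_code)
    dm <- matches_any_prefix(code, codes$dm_icd_prefixes)
    dmx <- dx[inwin & dm, , drop = FALSE]
    if (nrow(dmx) > 0) {
      uq <- unique(dmx[, c("patient_id", "quarter")])
      cnt <- table(uq$patient_id)
      ev$n_dm_quarters <- as.integer(cnt[ev$patient_id])
      ev$n_dm_quarters[is.na(ev$n_dm_quarters)] <- 0L
      codex <- normalise_icd(dmx$icd_code)
      ev$has_e10 <- flag(dmx$patient_id[startsWith(codex, codes$t1dm_prefix)])
      ev$has_e11 <- flag(dmx$patient_id[startsWith(codex, codes$t2dm_prefix)])
      ev$has_e12_14 <- flag(dmx$patient_id[matches_any_prefix(codex, e12_14)])
    }
  }

  # ED diagnoses of 2016 (no qualifier filter: facility diagnoses)
  vs <- tables$ed_visits
  ed_codes <- strsplit(ifelse(is.na(vs$ed_icd_codes), "", vs$ed_icd_codes), ";",
                       fixed = TRUE)
  ed_long <- data.frame(patient_id = rep(vs$patient_id, lengths(ed_codes)),
                        code = normalise_icd(unlist(ed_codes)),
                        stringsAsFactors = FALSE)
  ed_dm <- ed_long[matches_any_prefix(ed_long$code, codes$dm_icd_prefixes), ,
                   drop = FALSE]
  ev$has_ed_dm <- flag(ed_dm$patient_id)
  ev$has_e10 <- ev$has_e10 | flag(ed_dm$patient_id[startsWith(ed_dm$code, codes$t1dm_prefix)])
  ev$has_e11 <- ev$has_e11 | flag(ed_dm$patient_id[startsWith(ed_dm$code, codes$t2dm_prefix)])
  ev$has_e12_14 <- ev$has_e12_14 | flag(ed_dm$patient_id[matches_any_prefix(ed_dm$code, e12_14)])

  # main hospital diagnosis of admitted visits
  adm <- vs[vs$admitted & !is.na(vs$main_hospital_icd), , drop = FALSE]
  if (nrow(adm) > 0) {
    mh <- normalise_icd(adm$main_hospital_icd)
    hdm <- matches_any_prefix(mh, codes$dm_icd_prefixes)
    ev$has_hospital_dm <- flag(adm$patient_id[hdm])
    ev$has_e10 <- ev$has_e10 | flag(adm$patient_id[hdm & startsWith(mh, codes$t1dm_prefix)])
    ev$has_e11 <- ev$has_e11 | flag(adm$patient_id[hdm & startsWith(mh, codes$t2dm_prefix)])
    ev$has_e12_14 <- ev$has_e12_14 | flag(adm$patient_id[hdm & matches_any_prefix(mh, e12_14)])
  }

  # antidiabetic prescriptions in the 8-quarter lookback
  rx <- tables$prescriptions
  if (!is.null(rx) && nrow(rx) > 0) {
    qidx <- quarter_index(rx$quarter)
    iq <- idx_of[rx$patient_id]
    inwin <- !is.na(iq) & qidx >= iq - 8L & qidx <= iq - 1L
    atc <- toupper(rx$atc_code)
    ins <- inwin & startsWith(atc, codes$insulin_atc_prefix)
    oad <- inwin & startsWith(atc, codes$oad_atc_prefix)
    ev$has_insulin <- flag(rx$patient_id[ins])
    ev$has_oad <- flag(rx$patient_id[oad])
    ev$has_rx <- ev$has_insulin | ev$has_oad
  }

  # DMP enrolment
  dp <- tables$dmp
  if (!is.null(dp) && nrow(dp) > 0) {
    ev$t1dmp <- flag(dp$patient_id[dp$programme == "T1DMP"])
    ev$t2dmp <- flag(dp$patient_id[dp$programme == "T2DMP"])
  }

  # billing events also establish outpatient presence
  be <- tables$billing_events
  if (!is.null(be) && nrow(be) > 0) {
    ev$outpatient_present <- ev$outpatient_present | flag(be$patient_id)
  }
  ev
}

#' Step I: patients with any diabetes code
#'
#' Returns patients carrying at least one E10--E14 code among outpatient
#' diagnoses with qualifier "confirmed" or "condition after" in the eight
#' quarters before the index quarter, ED diagnoses of 2016, or the main
#' hospital diagnosis.  The qualifier filter applies to outpatient codes
#' only.
#'
#' @param tables a `claims_tables` list.
#' @param codes a [code_config()].
#' @return character vector of candidate patient ids.
#' @export
find_dm_candidates <- function(tables, codes = code_config()) {
  ev <- dm_evidence(tables, codes)
  ev$patient_id[ev$n_dm_quarters >= 1L | ev$has_ed_dm | ev$has_hospital_dm]
}

#' Step II: validate the diabetes diagnosis
#'
#' The four conditions are tested in order and the first satisfied one is
#' returned: (1) DM coded in at least two distinct lookback quarters;
#' (2) one lookback quarter plus a DM code among the 2016 ED diagnoses;
#' (3) at least one DM code (outpatient lookback or ED) plus at least one
#' insulin or OAD prescription in the lookback; (4) DM as main hospital
#' diagnosis.  Quarters need not be consecutive; diagnosis and prescription
#' may sit in different quarters.
#'
#' @param evidence data frame as built by the internal evidence assembly
#'   (columns `n_dm_quarters`, `has_ed_dm`, `has_rx`, `has_hospital_dm`).
#' @return integer vector: condition 1--4 or `NA` where validation fails.
#' @export
validate_dm <- function(evidence) {
  cond <- rep(NA_integer_, nrow(evidence))
  c1 <- evidence$n_dm_quarters >= 2L
  c2 <- !c1 & evidence$n_dm_quarters >= 1L & evidence$has_ed_dm
  c3 <- !c1 & !c2 & (evidence$n_dm_quarters >= 1L | evidence$has_ed_dm) &
    evidence$has_rx
  c4 <- !c1 & !c2 & !c3 & evidence$has_hospital_dm
  cond[c4] <- 4L; cond[c3] <- 3L; cond[c2] <- 2L; cond[c1] <- 1L
  cond
}

#' Step III: allocate the diabetes type
#'
#' Deterministic reconstruction of a type-allocation rule from the stated
#' ingredients (E10--E14 coding pattern, insulin/OAD prescriptions, DMP
#' enrolment): type 1 iff the patient has E10 codes without any E11,
#' insulin without OAD, or is enrolled in the type-1 DMP without the
#' type-2 one; otherwise type 2 iff E11 is coded or OAD prescribed or the
#' type-2 DMP attended; E12--E14-only coders under insulin-only therapy are
#' "other"; everything left is "unclear".  The rule is a documented
#' stand-in and can be replaced by post-processing the evidence columns.
#'
#' @param evidence evidence data frame (see [validate_dm()]); needs columns
#'   `has_e10`, `has_e11`, `has_e12_14`, `has_insulin`, `has_oad`,
#'   `t1dmp`, `t2dmp`.
#' @return character vector: "T2DM", "T1DM", "other" or "unclear".
#' @export
allocate_dm_type <- function(evidence) {
  t1 <- (evidence$has_e10 & !evidence$has_e11 &
           evidence$has_insulin & !evidence$has_oad) |
    (evidence$t1dmp & !evidence$t2dmp)
  t2 <- !t1 & (evidence$has_e11 | evidence$has_oad | evidence$t2dmp)
  oth <- !t1 & !t2 & evidence$has_e12_14 & evidence$has_insulin & !evidence$has_oad
  out <- rep("unclear", nrow(evidence))
  out[oth] <- "other"; out[t2] <- "T2DM"; out[t1] <- "T1DM"
  out
}

#' Build the validated T2DM study cohort
#'
#' Applies steps I--III and the final "at least one documented outpatient
#' case" filter; logs attrition counts at every funnel stage.
#'
#' @param tables a `claims_tables` list.
#' @param codes a [code_config()].
#' @return list with `members` (one row per cohort member: index visit,
#'   index quarter, validation condition, DM type, evidence counts) and
#'   `attrition` (named integer vector, non-increasing along the funnel).
#' @export
build_cohort <- function(tables, codes = code_config()) {
  empty <- data.frame(patient_id = character(), index_date = as.Date(character()),
                      index_quarter = character(), validation_condition = integer(),
                      dm_type = character(), stringsAsFactors = FALSE)
  zero_rep <- c(eligible = 0L, any_dm_code = 0L, validated_dm = 0L,
                t2dm = 0L, outpatient_case = 0L)
  if (is.null(tables$ed_visits) || nrow(tables$ed_visits) == 0) {
    return(list(members = empty, attrition = zero_rep))
  }
  ev <- dm_evidence(tables, codes)
  ev$validation_condition <- validate_dm(ev)
  candidate <- ev$n_dm_quarters >= 1L | ev$has_ed_dm | ev$has_hospital_dm
  validated <- candidate & !is.na(ev$validation_condition)
  ev$dm_type <- NA_character_
  ev$dm_type[validated] <- allocate_dm_type(ev[validated, , drop = FALSE])
  t2 <- validated & !is.na(ev$dm_type) & ev$dm_type == "T2DM"
  final <- t2 & ev$outpatient_present

  attrition <- c(eligible = nrow(ev),
                 any_dm_code = sum(candidate),
                 validated_dm = sum(validated),
                 t2dm = sum(t2),
                 outpatient_case = sum(final))
  members <- ev[final, c("patient_id", "index_date", "index_quarter",
                         "validation_condition", "dm_type", "n_dm_quarters",
                         "has_ed_dm", "has_hospital_dm", "has_insulin",
                         "has_oad", "t1dmp", "t2dmp"), drop = FALSE]
  rownames(members) <- NULL
  list(members = members, attrition = attrition)
}
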