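# Canonical definition of the indicator matrix: column order, category sets
# and human-readable category labels.  Every module that touches indicator
# profiles (generation, construction, imputation, LCA) goes through these.

#' Indicator columns in canonical order
#'
#' The eleven categorical indicators describing patient characteristics,
#' disease stage, health care utilisation and process quality of outpatient
#' care in the year before the index ED visit.  Creatinine measurement is
#' constructed like the other process-quality indicators and is typically
#' removed again by the local-independence screen before the LCA.
#'
#' @return character vector of column names.
#' @export
indicator_columns <- function() {
  c("sex", "age_cat", "complication_cat", "medication_cat",
    "gp_cat", "genspec_cat", "specspec_cat",
    "hba1c_cat", "microalb_cat", "creatinine_cat", "fundus_cat")
}

#' Category sets of the indicator columns
#'
#' Coding: sex male (1) / female (2); age 0--55 (1), 56--70 (2), 71--85 (3),
#' >= 86 (4); complication groups 0 (0), 1--2 (1), >= 3 (2); medication none
#' (0), OAD only (1), insulin only (2), OAD and insulin (3); every
#' quarter-count indicator 0 quarters (0), 1--2 (1), 3--4 (2).
#'
#' @return named list of integer vectors (allowed category codes per column).
#' @export
indicator_levels <- function() {
  q3 <- 0:2
  list(sex = 1:2, age_cat = 1:4, complication_cat = 0:2, medication_cat = 0:3,
       gp_cat = q3, genspec_cat = q3, specspec_cat = q3,
       hba1c_cat = q3, microalb_cat = q3, creatinine_cat = q3, fundus_cat = q3)
}

# map a distinct-quarter count (0..4) to its 3-level category
categorise_quarters <- function(count) {
  stopifnot(all(count >= 0 & count <= 4))
  ifelse(count == 0L, 0L, ifelse(count <= 2L, 1L, 2L))
}

# map a complication-group count to its 3-level category
categorise_complications <- function(count) {
  ifelse(count == 0L, 0L, ifelse(count <= 2L, 1L, 2L))
}

# age in years -> 4-level category
categorise_age <- function(age) {
  stopifnot(all(age >= 0))
  findInterval(age, c(0, 56, 71, 86))
}

# check a completed or partially missing indicator data.frame against the
# canonical category sets; returns the data.frame invisibly
assert_indicator_matrix <- function(x, allow_missing = TRUE) {
  lv <- indicator_levels()
  cols <- intersect(indicator_columns(), names(x))
  if (length(cols) == 0L) stop("no indicator columns found")
  for (cl in cols) {
    v <- x[[cl]]
    bad <- !is.na(v) & !(v %in% lv[[cl]])
    if (any(bad)) {
      stop(sprintf("column '%s' holds values outside its category set: %s",
                   cl, paste(unique(v[bad]), collapse = ", ")))
    }
    if (!allow_missing && anyNA(v)) {
      stop(sprintf("column '%s' holds missing values", cl))
    }
  }
  invisible(x)
}
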