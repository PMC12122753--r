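# Code configuration: ICD-10-GM / ATC prefixes for diabetes, billing-code
# sets for the process-quality indicators, the DM complication-group map and
# the Charlson comorbidity mapping.  All sets are overridable so that users
# with access to real regional billing catalogues can substitute their own.

#' Default code configuration
#'
#' @param dm_icd_prefixes ICD-10 stems identifying any diabetes mellitus.
#' @param t2dm_prefix,t1dm_prefix stems for type 2 and type 1 DM.
#' @param insulin_atc_prefix,oad_atc_prefix ATC prefixes for insulin and
#'   oral antidiabetic drug prescriptions.
#' @param hba1c_codes,microalbuminuria_codes,creatinine_codes,fundus_codes
#'   billing-code sets for the four process-quality indicators.  The
#'   defaults are synthetic placeholder codes: real outpatient billing
#'   numbers are regionally versioned and must be supplied by the user.
#' @param complication_group_map named character vector mapping the fourth
#'   ICD digit of an E10--E14 code to a DM complication group; digits not in
#'   the map (including ".9", "without complications") contribute no group.
#' @param charlson_map data frame with columns `condition`, `prefixes`
#'   (comma-separated ICD-10 prefixes) and `weight`; defaults to the Quan
#'   ICD-10 coding algorithm with the original Charlson weights.
#' @param specialty_groups allowed physician specialty group labels.
#' @return a list of class `code_config`.
#' @export
code_config <- function(dm_icd_prefixes = c("E10", "E11", "E12", "E13", "E14"),
                        t2dm_prefix = "E11",
                        t1dm_prefix = "E10",
                        insulin_atc_prefix = "A10A",
                        oad_atc_prefix = "A10B",
                        hba1c_codes = "LAB-HBA1C",
                        microalbuminuria_codes = "LAB-MALB",
                        creatinine_codes = "LAB-CREA",
                        fundus_codes = "OPH-FUNDUS",
                        complication_group_map = c(
                          "0" = "metabolic", "1" = "metabolic",
                          "2" = "kidney", "3" = "eye",
                          "4" = "neuro_vascular", "5" = "neuro_vascular",
                          "7" = "multiple"),
                        charlson_map = charlson_quan_icd10(),
                        specialty_groups = c("GP", "general_specialist",
                                             "specialised_specialist", "other")) {
  cfg <- list(dm_icd_prefixes = dm_icd_prefixes,
              t2dm_prefix = t2dm_prefix,
              t1dm_prefix = t1dm_prefix,
              insulin_atc_prefix = insulin_atc_prefix,
              oad_atc_prefix = oad_atc_prefix,
              hba1c_codes = hba1c_codes,
              microalbuminuria_codes = microalbuminuria_codes,
              creatinine_codes = creatinine_codes,
              fundus_codes = fundus_codes,
              complication_group_map = complication_group_map,
              charlson_map = charlson_map,
              specialty_groups = specialty_groups)
  class(cfg) <- "code_config"
  validate_code_config(cfg)
}

validate_code_config <- function(cfg) {
  stopifnot(length(cfg$dm_icd_prefixes) > 0,
            cfg$t2dm_prefix %in% cfg$dm_icd_prefixes,
            cfg$t1dm_prefix %in% cfg$dm_icd_prefixes)
  sets <- list(cfg$hba1c_codes, cfg$microalbuminuria_codes,
               cfg$creatinine_codes, cfg$fundus_codes)
  all_codes <- unlist(sets)
  if (anyDuplicated(all_codes)) {
    stop("billing-code sets must be pairwise disjoint")
  }
  stopifnot(is.data.frame(cfg$charlson_map),
            all(c("condition", "prefixes", "weight") %in% names(cfg$charlson_map)))
  invisible(cfg)
}

#' Quan ICD-10 Charlson mapping with original weights
#'
#' Seventeen comorbid condition groups identified by ICD-10 code prefixes
#' (dots stripped), each with its original Charlson weight.  Hierarchy rules
#' (applied in [charlson_score()]): complicated diabetes supersedes
#' uncomplicated diabetes, moderate/severe liver disease supersedes mild
#' liver disease, and metastatic solid tumour supersedes any malignancy.
#'
#' @return data frame with columns `condition`, `prefixes`, `weight`.
#' @export
charlson_quan_icd10 <- function() {
  data.frame(
    condition = c("myocardial_infarction", "congestive_heart_failure",
                  "peripheral_vascular", "cerebrovascular", "dementia",
                  "chronic_pulmonary", "rheumatic", "peptic_ulcer",
                  "mild_liver", "diabetes_uncomplicated",
                  "diabetes_complicated", "hemiplegia_paraplegia",
                  "renal", "any_malignancy", "moderate_severe_liver",
                  "metastatic_solid_tumour", "aids_hiv"),
    prefixes = c(
      "I21,I22,I252",
      "I099,I110,I130,I132,I255,I420,I425,I426,I427,I428,I429,I43,I50,P290",
      "I70,I71,I731,I738,I739,I771,I790,I792,K551,K558,K559,Z958,Z959",
      "G45,G46,H340,I60,I61,I62,I63,I64,I65,I66,I67,I68,I69",
      "F00,F01,F02,F03,F051,G30,G311",
      "I278,I279,J40,J41,J42,J43,J44,J45,J46,J47,J60,J61,J62,J63,J64,J65,J66,J67,J684,J701,J703",
      "M05,M06,M315,M32,M33,M34,M351,M353,M360",
      "K25,K26,K27,K28",
      "B18,K700,K701,K702,K703,K709,K713,K714,K715,K717,K73,K74,K760,K762,K763,K764,K768,K769,Z944",
      "E100,E101,E106,E108,E109,E110,E111,E116,E118,E119,E120,E121,E126,E128,E129,E130,E131,E136,E138,E139,E140,E141,E146,E148,E149",
      "E102,E103,E104,E105,E107,E112,E113,E114,E115,E117,E122,E123,E124,E125,E127,E132,E133,E134,E135,E137,E142,E143,E144,E145,E147",
      "G041,G114,G801,G802,G81,G82,G830,G831,G832,G833,G834,G839",
      "I120,I131,N032,N033,N034,N035,N036,N037,N052,N053,N054,N055,N056,N057,N18,N19,N250,Z490,Z491,Z492,Z940,Z992",
      "C00,C01,C02,C03,C04,C05,C06,C07,C08,C09,C10,C11,C12,C13,C14,C15,C16,C17,C18,C19,C20,C21,C22,C23,C24,C25,C26,C30,C31,C32,C33,C34,C37,C38,C39,C40,C41,C43,C45,C46,C47,C48,C49,C50,C51,C52,C53,C54,C55,C56,C57,C58,C60,C61,C62,C63,C64,C65,C66,C67,C68,C69,C70,C71,C72,C73,C74,C75,C76,C81,C82,C83,C84,C85,C88,C90,C91,C92,C93,C94,C95,C96,C97",
      "I850,I859,I864,I982,K704,K711,K721,K729,K765,K766,K767",
      "C77,C78,C79,C80",
      "B20,B21,B22,B24"),
    weight = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 6, 6),
    stringsAsFactors = FALSE)
}

# normalise ICD codes: upper case, dots stripped
normalise_icd <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

# TRUE where a (normalised) code starts with any of the given prefixes
matches_any_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
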