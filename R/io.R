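# Plain-CSV persistence of the claims tables and indicator matrices.

#' Write claims tables as CSV files
#'
#' One file per table (`patients.csv`, `outpatient_diagnoses.csv`,
#' `billing_events.csv`, `prescriptions.csv`, `ed_visits.csv`, `dmp.csv`)
#' with the documented headers; missing values are written as `NA`.
#'
#' @param tables a `claims_tables` list.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_claims_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "NA")
    p
  }, character(1))
  truth <- attr(tables, "truth")
  if (!is.null(truth)) {
    p <- file.path(dir, "true_labels.csv")
    utils::write.csv(truth, p, row.names = FALSE, na = "NA")
    files <- c(files, p)
  }
  invisible(files)
}

#' Read claims tables from a CSV directory
#'
#' Inverse of [write_claims_tables()].
#'
#' @param dir directory holding the six table CSVs.
#' @return a `claims_tables` list.
#' @export
read_claims_tables <- function(dir) {
  nms <- c("patients", "outpatient_diagnoses", "billing_events",
           "prescriptions", "ed_visits", "dmp")
  tables <- lapply(nms, function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing table file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  names(tables) <- nms
  tables$ed_visits$visit_date <- as.Date(tables$ed_visits$visit_date)
  if ("admitted" %in% names(tables$ed_visits)) {
    tables$ed_visits$admitted <- as.logical(tables$ed_visits$admitted)
  }
  class(tables) <- "claims_tables"
  p <- file.path(dir, "true_labels.csv")
  if (file.exists(p)) {
    attr(tables, "truth") <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  tables
}
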