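# Class characterisation: descriptive profiles per latent class, top coded
# diagnoses, and univariate / age-adjusted logistic odds-ratio regression
# of the dichotomous outcomes (recurrent ED visits, inpatient admission).

count_ed_codes <- function(ed_icd_codes) {
  lengths(strsplit(ifelse(is.na(ed_icd_codes) | ed_icd_codes == "", NA,
                          ed_icd_codes), ";", fixed = TRUE))
}

#' Flag EDs with outlying diagnosis counts
#'
#' The default rule excludes sites whose mean number of documented
#' diagnoses per visit exceeds the cross-site mean of those means by more
#' than `sd_multiplier` cross-site standard deviations; an absolute
#' threshold can be used instead.
#'
#' @param ed_visits ED visit table (`site_id`, `ed_icd_codes`).
#' @param sd_multiplier z-threshold on the site means (default 3).
#' @param absolute if not `NULL`, exclude sites with mean
#'   diagnoses-per-visit above this value instead.
#' @return integer vector of excluded site ids (possibly empty).
#' @export
site_outlier_filter <- function(ed_visits, sd_multiplier = 3, absolute = NULL) {
  k <- count_ed_codes(ed_visits$ed_icd_codes)
  k[is.na(k)] <- 0L
  m <- tapply(k, ed_visits$site_id, mean)
  if (length(m) < 2L) {
    warning("fewer than two ED sites; nothing excluded")
    return(integer(0))
  }
  if (!is.null(absolute)) {
    return(as.integer(names(m)[m > absolute]))
  }
  s <- stats::sd(m)
  if (s == 0) return(integer(0))
  z <- (m - mean(m)) / s
  as.integer(names(m)[z > sd_multiplier])
}

#' Most frequent three-digit diagnoses
#'
#' Counts ICD codes truncated to their first three characters (dots
#' stripped) over ED visits or over main hospital diagnoses of admitted
#' visits.  Repeated visits of one patient count repeatedly.  Ties break
#' lexicographically.
#'
#' @param tables a `claims_tables` list.
#' @param assignment optional data frame (`patient_id`, `class`); when
#'   given, per-class rankings are added and counting is restricted to the
#'   assigned patients.
#' @param source `"ed"` (all ED diagnoses) or `"main_hospital"` (main
#'   hospital diagnosis of admitted visits).
#' @param level truncation length (default 3).
#' @param n list length (default 10).
#' @param exclude_sites site ids to drop (see [site_outlier_filter()]).
#' @return list with `overall` (data frame `code`, `count`) and, given an
#'   assignment, `per_class` (one such data frame per class).
#' @export
top_diagnoses <- function(tables, assignment = NULL,
                          source = c("ed", "main_hospital"),
                          level = 3L, n = 10L, exclude_sites = NULL) {
  source <- match.arg(source)
  v <- tables$ed_visits
  if (!is.null(exclude_sites)) v <- v[!(v$site_id %in% exclude_sites), , drop = FALSE]
  if (!is.null(assignment)) {
    v <- v[v$patient_id %in% assignment$patient_id, , drop = FALSE]
  }
  if (source == "ed") {
    codes <- strsplit(ifelse(is.na(v$ed_icd_codes), "", v$ed_icd_codes), ";",
                      fixed = TRUE)
    long <- data.frame(patient_id = rep(v$patient_id, lengths(codes)),
                       code = unlist(codes), stringsAsFactors = FALSE)
    long <- long[long$code != "", , drop = FALSE]
  } else {
    adm <- v[v$admitted & !is.na(v$main_hospital_icd), , drop = FALSE]
    long <- data.frame(patient_id = adm$patient_id,
                       code = adm$main_hospital_icd, stringsAsFactors = FALSE)
  }
  long$code <- substr(normalise_icd(long$code), 1L, level)
  rank_codes <- function(x) {
    if (nrow(x) == 0) {
      return(data.frame(code = character(), count = integer()))
    }
    tb <- table(x$code)
    df <- data.frame(code = names(tb), count = as.integer(tb),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$code), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, n)
  }
  out <- list(overall = rank_codes(long))
  if (!is.null(assignment)) {
    cls <- assignment$class[match(long$patient_id, assignment$patient_id)]
    out$per_class <- lapply(sort(unique(assignment$class)), function(k) {
      rank_codes(long[!is.na(cls) & cls == k, , drop = FALSE])
    })
    names(out$per_class) <- paste0("class_", sort(unique(assignment$class)))
  }
  out
}

#' Descriptive profiles of the latent classes
#'
#' Hard-MAP empirical summaries per class: size and share, the category
#' distribution and mean category code of every indicator, the Charlson
#' category distribution when available, and outcome rates.
#'
#' @param assignment integer MAP class per row of `matrix`.
#' @param matrix indicator data frame (completed or observed).
#' @param outcomes optional data frame with logical `recurrent_ed` and
#'   `admitted` aligned with `matrix` rows.
#' @param charlson_cat optional character vector of Charlson categories.
#' @return list of class `class_profiles`: `shares`, `sizes`, and per
#'   class the indicator `distributions`, `mean_codes` and `outcome_rates`.
#' @export
class_profiles <- function(assignment, matrix, outcomes = NULL,
                           charlson_cat = NULL) {
  x <- as.data.frame(matrix)
  if ("patient_id" %in% names(x)) x$patient_id <- NULL
  stopifnot(nrow(x) == length(assignment))
  cols <- intersect(indicator_columns(), names(x))
  lv <- indicator_levels()
  ks <- sort(unique(assignment))
  sizes <- vapply(ks, function(k) sum(assignment == k), integer(1))
  names(sizes) <- paste0("class_", ks)
  per_class <- lapply(ks, function(k) {
    rows <- assignment == k
    dist <- lapply(cols, function(cl) {
      tb <- table(factor(x[[cl]][rows], levels = lv[[cl]]))
      as.numeric(tb) / max(sum(tb), 1L)
    })
    names(dist) <- cols
    means <- vapply(cols, function(cl) mean(x[[cl]][rows], na.rm = TRUE),
                    numeric(1))
    out <- list(size = sum(rows), share = mean(assignment == k),
                distributions = dist, mean_codes = means)
    if (!is.null(outcomes)) {
      out$outcome_rates <- c(
        recurrent_ed = mean(outcomes$recurrent_ed[rows]),
        admitted = mean(outcomes$admitted[rows]))
    }
    if (!is.null(charlson_cat)) {
      tb <- table(factor(charlson_cat[rows],
                         levels = c("0", "1-2", "3-4", ">=5")))
      out$charlson_distribution <- as.numeric(tb) / max(sum(tb), 1L)
      names(out$charlson_distribution) <- names(tb)
    }
    out
  })
  names(per_class) <- paste0("class_", ks)
  structure(list(shares = sizes / length(assignment), sizes = sizes,
                 classes = per_class), class = "class_profiles")
}

#' Logistic odds-ratio regression of a dichotomous outcome on class
#'
#' Maximum-likelihood logistic fit (IRLS via `glm`, score-equation
#' tolerance `1e-10`); odds ratios are exponentiated coefficients with
#' Wald confidence intervals from the observed-information covariance.
#' Class 1 is the reference.  With a single categorical predictor the
#' fitted OR equals the contingency-table cross-product ratio.
#'
#' @param outcome logical/0-1 outcome vector.
#' @param class_assignment integer class per observation.
#' @param age_cat optional age category for adjustment; when supplied the
#'   model is `outcome ~ class + age`.
#' @param weights optional case weights (for aggregated count data).
#' @param conf_level confidence level of the Wald interval.
#' @return data frame of class `regression_result`: `term`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `adjusted`, `reference`.
#' @export
logistic_or <- function(outcome, class_assignment, age_cat = NULL,
                        weights = NULL, conf_level = 0.95) {
  y <- as.integer(outcome)
  stopifnot(all(y %in% 0:1))
  cl <- factor(class_assignment)
  if (is.null(weights)) weights <- rep(1, length(y))
  # separation guard: a class with all-0 or all-1 outcomes has no finite OR
  agg <- tapply(weights * y, cl, sum)
  tot <- tapply(weights, cl, sum)
  zero <- agg == 0 | agg == tot
  if (any(zero)) {
    stop("outcome is constant within class ",
         paste(names(agg)[zero], collapse = ", "),
         "; odds ratios are not identifiable")
  }
  df <- data.frame(y = y, cl = cl, w = weights)
  fm <- y ~ cl
  if (!is.null(age_cat)) {
    df$age <- factor(age_cat)
    fm <- y ~ cl + age
  }
  fit <- stats::glm(fm, family = stats::binomial(), data = df, weights = w,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- grep("^(cl|age)", names(est))
  out <- data.frame(
    term = sub("^cl", "class ", sub("^age", "age ", names(est)[keep])),
    or = exp(est[keep]),
    ci_low = exp(est[keep] - z * se[keep]),
    ci_high = exp(est[keep] + z * se[keep]),
    p_value = 2 * stats::pnorm(-abs(est[keep] / se[keep])),
    adjusted = !is.null(age_cat),
    reference = paste("class", levels(cl)[1]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Odds ratios from an events / non-events table
#'
#' Convenience wrapper reconstructing the aggregated individual-level data
#' from per-class event and non-event counts and fitting [logistic_or()].
#'
#' @param events,non_events integer vectors of per-class counts (class 1
#'   first).
#' @return a `regression_result` data frame.
#' @export
odds_ratio_from_counts <- function(events, non_events) {
  K <- length(events)
  stopifnot(length(non_events) == K)
  cl <- rep(rep(seq_len(K), 2L), c(events, non_events))
  y <- rep(rep(c(1L, 0L), each = K), c(events, non_events))
  logistic_or(y, cl)
}

#' Write the analysis report bundle
#'
#' Emits the pipeline's numeric outputs as plain CSV/JSON files: attrition
#' counts, the fit-criteria table over K (BIC / ASW / ICL curves), the
#' selection trace, class profiles, top-ten diagnosis tables, regression
#' results and a run manifest (seed and configuration echo).  Identical
#' seed and configuration produce byte-identical manifests.
#'
#' @param results result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_report_bundle <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  put_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <<- c(files, p)
  }
  if (!is.null(results$attrition)) {
    put_csv(data.frame(stage = names(results$attrition),
                       n = as.integer(results$attrition)), "attrition.csv")
  }
  if (!is.null(results$fit)) put_csv(results$fit$summary, "fit_criteria.csv")
  if (!is.null(results$selection)) {
    put_json(list(candidates = as.list(results$selection$candidates),
                  chosen_k = results$selection$chosen_k,
                  failed = results$selection$failed,
                  trace = results$selection$trace), "selection.json")
  }
  if (!is.null(results$profiles)) {
    pr <- results$profiles
    shares <- data.frame(class = names(pr$sizes), size = as.integer(pr$sizes),
                         share = as.numeric(pr$shares))
    put_csv(shares, "class_shares.csv")
    dist_rows <- do.call(rbind, lapply(names(pr$classes), function(k) {
      cls <- pr$classes[[k]]
      do.call(rbind, lapply(names(cls$distributions), function(cl) {
        data.frame(class = k, indicator = cl,
                   category = indicator_levels()[[cl]],
                   proportion = cls$distributions[[cl]])
      }))
    }))
    put_csv(dist_rows, "class_indicator_distributions.csv")
    means <- do.call(rbind, lapply(names(pr$classes), function(k) {
      data.frame(class = k, indicator = names(pr$classes[[k]]$mean_codes),
                 mean_code = as.numeric(pr$classes[[k]]$mean_codes))
    }))
    put_csv(means, "class_mean_codes.csv")
  }
  if (!is.null(results$top_ed)) {
    put_csv(results$top_ed$overall, "top10_ed_diagnoses.csv")
  }
  if (!is.null(results$top_hospital)) {
    put_csv(results$top_hospital$overall, "top10_hospital_diagnoses.csv")
  }
  if (!is.null(results$regression)) {
    put_csv(results$regression, "odds_ratios.csv")
  }
  put_json(list(seed = results$seed, n_patients = results$n_patients,
                chosen_k = if (!is.null(results$selection))
                  results$selection$chosen_k else NA,
                generated = "claimslca"), "manifest.json")
  invisible(files)
}
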