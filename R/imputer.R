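# Iterative, fully conditional random-forest imputation of the categorical
# indicator matrix: each variable with missing cells is regressed on all
# others with a classification forest, looping until the fraction of
# imputed cells that change stops decreasing or the iteration cap is hit.

#' Impute missing indicator categories
#'
#' Missing cells are initialised with the per-variable mode, then variables
#' are visited in order of increasing missingness; for each, a
#' classification forest (100 trees by default, majority vote) is trained
#' on the rows observed for that variable and used to predict its missing
#' cells.  Iteration stops at `max_iter` or as soon as the per-iteration
#' change fraction increases over the previous iteration.  Observed cells
#' are never touched.
#'
#' @param matrix data frame holding the indicator columns (additional
#'   columns such as `patient_id` are passed through untouched).
#' @param max_iter iteration cap (default 10).
#' @param seed integer master seed; per-iteration forest seeds are derived
#'   from it, making the result reproducible.
#' @param num_trees trees per forest.
#' @return object of class `imputation_result`: list with `completed`
#'   (the matrix without missing indicator cells), `n_iterations_run`,
#'   `change_fractions` (per-iteration fraction of imputed cells that
#'   changed) and `seed`.
#' @export
impute_indicators <- function(matrix, max_iter = 10L, seed = 1L,
                              num_trees = 100L) {
  cols <- intersect(indicator_columns(), names(matrix))
  if (length(cols) < 2L) stop("need at least two indicator variables")
  assert_indicator_matrix(matrix, allow_missing = TRUE)
  lv <- indicator_levels()

  x <- matrix[, cols, drop = FALSE]
  miss <- is.na(as.matrix(x))
  fully_missing <- cols[colSums(!miss) == 0L]
  if (length(fully_missing) > 0) {
    stop("variable(s) with no observed values: ",
         paste(fully_missing, collapse = ", "))
  }

  result <- function(completed_x, iters, changes) {
    completed <- matrix
    completed[, cols] <- completed_x
    structure(list(completed = completed, n_iterations_run = iters,
                   change_fractions = changes, seed = seed),
              class = "imputation_result")
  }
  if (!any(miss)) return(result(x, 0L, numeric(0)))

  # factor frame with full level sets so predictions stay in-range
  fx <- as.data.frame(lapply(cols, function(cl) {
    factor(x[[cl]], levels = lv[[cl]])
  }))
  names(fx) <- cols

  mode_of <- function(f) {
    tb <- table(f)
    names(tb)[which.max(tb)]
  }
  for (cl in cols) {
    m <- is.na(fx[[cl]])
    if (any(m)) fx[[cl]][m] <- mode_of(fx[[cl]][!m])
  }

  visit <- cols[colSums(miss) > 0L]
  visit <- visit[order(colSums(miss)[match(visit, cols)])]

  changes <- numeric(0)
  prev_change <- Inf
  iters <- 0L
  n_missing <- sum(miss)
  for (it in seq_len(max_iter)) {
    before <- fx
    for (v in seq_along(visit)) {
      cl <- visit[v]
      m <- miss[, match(cl, cols)]
      fit <- ranger::ranger(
        dependent.variable.name = cl,
        data = fx[!m, , drop = FALSE],
        num.trees = num_trees, num.threads = 1L,
        seed = derive_seed(seed, it * 100L + v),
        verbose = FALSE)
      pred <- stats::predict(fit, data = fx[m, , drop = FALSE],
                             num.threads = 1L,
                             seed = derive_seed(seed, it * 100L + v + 50L))$predictions
      fx[[cl]][m] <- pred
    }
    iters <- it
    changed <- 0L
    for (j in seq_along(cols)) {
      m <- miss[, j]
      changed <- changed + sum(before[[cols[j]]][m] != fx[[cols[j]]][m])
    }
    this_change <- changed / n_missing
    changes <- c(changes, this_change)
    if (it > 1L && this_change > prev_change) break
    if (this_change == 0) break
    prev_change <- this_change
  }

  completed_x <- x
  for (cl in cols) {
    completed_x[[cl]] <- as.integer(as.character(fx[[cl]]))
  }
  # observed cells must be untouched
  stopifnot(identical(as.matrix(completed_x)[!miss], as.matrix(x)[!miss]))
  result(completed_x, iters, changes)
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Indicator imputation: %d iteration(s), change fractions: %s\n",
              x$n_iterations_run,
              paste(signif(x$change_fractions, 3), collapse = ", ")))
  invisible(x)
}
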