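# Calendar-quarter helpers.  Quarters are carried through all tables as
# strings "YYYYQn" and converted to a linear index (year * 4 + quarter - 1)
# for window arithmetic.

#' Build quarter labels
#'
#' @param year integer vector of calendar years.
#' @param q integer vector of quarters (1--4).
#' @return character vector like `"2016Q3"`.
#' @export
quarter_label <- function(year, q) {
  stopifnot(all(q %in% 1:4))
  sprintf("%dQ%d", as.integer(year), as.integer(q))
}

#' Linear index of a quarter label
#'
#' Maps `"YYYYQn"` to `year * 4 + (n - 1)` so that consecutive quarters
#' differ by one.
#'
#' @param quarter character vector of quarter labels.
#' @return integer vector.
#' @export
quarter_index <- function(quarter) {
  m <- regmatches(quarter, regexec("^([0-9]{4})Q([1-4])$", quarter))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed quarter label(s): ", paste(unique(quarter[bad]), collapse = ", "))
  }
  yr <- as.integer(vapply(m, `[`, character(1), 2L))
  qq <- as.integer(vapply(m, `[`, character(1), 3L))
  yr * 4L + qq - 1L
}

#' Quarter label from a linear index
#' @param idx integer vector as produced by [quarter_index()].
#' @return character vector of quarter labels.
#' @export
quarter_from_index <- function(idx) {
  idx <- as.integer(idx)
  quarter_label(idx %/% 4L, idx %% 4L + 1L)
}

#' Calendar quarter of a date
#' @param date a `Date` vector.
#' @return character vector of quarter labels.
#' @export
quarter_of_date <- function(date) {
  date <- as.Date(date)
  quarter_label(as.integer(format(date, "%Y")),
                (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L)
}

#' Lookback window before an index quarter
#'
#' Returns the `n` calendar quarters immediately preceding the index
#' quarter, index quarter excluded, in ascending order.  The one-year
#' indicator window uses `n = 4`; diagnosis validation uses `n = 8`
#' ("two years prior").
#'
#' @param index_quarter quarter label of the index ED visit.
#' @param n window length, 4 or 8.
#' @return character vector of `n` quarter labels.
#' @export
#' @examples
#' lookback_quarters("2016Q3", 4)  # 2015Q3 2015Q4 2016Q1 2016Q2
lookback_quarters <- function(index_quarter, n = 4L) {
  stopifnot(length(index_quarter) == 1L, n %in% c(4L, 8L))
  i <- quarter_index(index_quarter)
  quarter_from_index(seq.int(i - n, i - 1L))
}

# round half away from zero (positive inputs only in this package);
# base round() would round 70.5 to 70
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# derived sub-seed kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + as.numeric(offset) * 7919) %% 2147483629)
}
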