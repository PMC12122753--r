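# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (explicit pair enumeration, direct summation) so they
# stay independent of the implementation they check.

# small well-separated K-class spec over the canonical indicator columns
make_test_spec <- function(K = 3, outcome = FALSE) {
  lv <- indicator_levels()
  peaked <- function(C, k) {
    # class k peaks on category ((k - 1) %% C) + 1
    m <- matrix(0.1 / (C - 1), K, C)
    for (i in seq_len(K)) m[i, (i - 1) %% C + 1] <- 0.9
    m / rowSums(m)
  }
  ir <- lapply(lv, function(vals) peaked(length(vals), K))
  olo <- NULL
  if (outcome) {
    olo <- list(admitted = list(intercept = 0, offsets = seq_len(K) - 1),
                recurrent_ed = list(intercept = -1, offsets = rep(0, K)))
  }
  latent_class_spec(class_weights = rep(1 / K, K), item_response = ir,
                    outcome_log_odds = olo)
}

# brute-force silhouette via the full pairwise simple-matching matrix
silhouette_brute <- function(x, cl) {
  x <- as.matrix(x)
  n <- nrow(x); J <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(x[i, ] != x[j, ]) / J
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sum(cl == own) <= 1) { s[i] <- 0; next }
    a <- mean(d[i, cl == own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), own),
                    function(k) mean(d[i, cl == k]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# pair-enumeration ARI / Jaccard
pair_indices_brute <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  total <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  ari <- if (max_index == expected) 1 else (n11 - expected) / (max_index - expected)
  list(ari = ari, jaccard = n11 / (n11 + n10 + n01))
}

# direct product-and-normalise posterior for one response row
posterior_brute <- function(model, row) {
  K <- model$K
  w <- numeric(K)
  for (k in seq_len(K)) {
    p <- model$pi[k]
    for (nm in model$columns) {
      c_idx <- match(row[[nm]], model$levels[[nm]])
      p <- p * model$theta[[nm]][c_idx, k]
    }
    w[k] <- p
  }
  w / sum(w)
}

# closed-form one-class log-likelihood: independent multinomial marginals
loglik_k1_brute <- function(x) {
  n <- nrow(x)
  ll <- 0
  for (j in seq_len(ncol(x))) {
    cnt <- table(x[[j]])
    ll <- ll + sum(cnt * log(cnt / n))
  }
  as.numeric(ll)
}

# hand-rolled claims tables for cohort unit tests: one patient, fully
# controllable events
single_patient_tables <- function(patient_id = "P1",
                                  index_date = as.Date("2016-08-15"),
                                  dx = NULL, rx = NULL, billing = NULL,
                                  ed_codes = "I10", admitted = FALSE,
                                  main_icd = NA_character_, dmp = NULL,
                                  extra_visits = NULL) {
  patients <- data.frame(patient_id = patient_id, sex = 1L, birth_year = 1950L,
                         region_id = 1L, insurance_status = "member",
                         rx_transmitted = TRUE, stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = patient_id, visit_date = index_date,
                       site_id = 1L, ed_icd_codes = ed_codes,
                       admitted = admitted, main_hospital_icd = main_icd,
                       stringsAsFactors = FALSE)
  if (!is.null(extra_visits)) visits <- rbind(visits, extra_visits)
  empty_dx <- data.frame(patient_id = character(), quarter = character(),
                         icd_code = character(), qualifier = character(),
                         stringsAsFactors = FALSE)
  empty_rx <- data.frame(patient_id = character(), quarter = character(),
                         atc_code = character(), stringsAsFactors = FALSE)
  empty_be <- data.frame(patient_id = character(), quarter = character(),
                         billing_code = character(), specialty_group = character(),
                         stringsAsFactors = FALSE)
  empty_dmp <- data.frame(patient_id = character(), programme = character(),
                          quarter = character(), stringsAsFactors = FALSE)
  tables <- list(patients = patients,
                 outpatient_diagnoses = if (is.null(dx)) empty_dx else dx,
                 billing_events = if (is.null(billing)) empty_be else billing,
                 prescriptions = if (is.null(rx)) empty_rx else rx,
                 ed_visits = visits,
                 dmp = if (is.null(dmp)) empty_dmp else dmp)
  class(tables) <- "claims_tables"
  tables
}

dx_row <- function(id, quarter, code, qualifier = "confirmed") {
  data.frame(patient_id = id, quarter = quarter, icd_code = code,
             qualifier = qualifier, stringsAsFactors = FALSE)
}

rx_row <- function(id, quarter, atc) {
  data.frame(patient_id = id, quarter = quarter, atc_code = atc,
             stringsAsFactors = FALSE)
}

be_row <- function(id, quarter, code = "GOP-CONS", specialty = "GP") {
  data.frame(patient_id = id, quarter = quarter, billing_code = code,
             specialty_group = specialty, stringsAsFactors = FALSE)
}
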