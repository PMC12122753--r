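# Profile- and claims-layer generator behaviour.

test_that("quarter arithmetic round-trips and lookback windows are correct", {
  expect_equal(quarter_index("2016Q1") - quarter_index("2015Q4"), 1L)
  expect_equal(quarter_from_index(quarter_index("2014Q3")), "2014Q3")
  expect_equal(quarter_of_date(as.Date("2016-07-01")), "2016Q3")
  expect_equal(lookback_quarters("2016Q3", 4),
               c("2015Q3", "2015Q4", "2016Q1", "2016Q2"))
  expect_equal(lookback_quarters("2016Q1", 4),
               c("2015Q1", "2015Q2", "2015Q3", "2015Q4"))
  expect_equal(lookback_quarters("2016Q2", 8),
               c("2014Q2", "2014Q3", "2014Q4", "2015Q1",
                 "2015Q2", "2015Q3", "2015Q4", "2016Q1"))
  expect_error(quarter_index("2016-03"), "malformed")
})

test_that("a one-class spec yields identical labels and theta-consistent marginals", {
  spec <- make_test_spec(K = 1)
  pr <- sample_indicator_profiles(spec, 20000, seed = 4)
  expect_true(all(pr$labels == 1L))
  lv <- indicator_levels()
  for (nm in c("sex", "medication_cat", "hba1c_cat")) {
    emp <- as.numeric(table(factor(pr$profiles[[nm]], levels = lv[[nm]]))) / 20000
    expect_lt(max(abs(emp - spec$item_response[[nm]][1, ])), 0.02)
  }
})

test_that("empirical class counts follow the study-share weights", {
  spec <- default_class_spec()
  n <- 40561
  pr <- sample_indicator_profiles(spec, n, seed = 11)
  counts <- tabulate(pr$labels, 3)
  expected <- n * spec$class_weights  # about (14805, 10586, 15170)
  for (k in 1:3) {
    tol <- 4 * sqrt(n * spec$class_weights[k] * (1 - spec$class_weights[k]))
    expect_lt(abs(counts[k] - expected[k]), tol)
  }
})

test_that("class frequencies pass a goodness-of-fit check across seeds", {
  spec <- default_class_spec()
  rejected <- 0L
  for (s in 1:20) {
    lab <- sample_indicator_profiles(spec, 50000, seed = 100 + s)$labels
    p <- stats::chisq.test(tabulate(lab, 3), p = spec$class_weights)$p.value
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 2L)
})

test_that("identical theta across classes carries no label information", {
  K <- 2
  lv <- indicator_levels()
  ir <- lapply(lv, function(vals) {
    p <- rep(1 / length(vals), length(vals))
    rbind(p, p)
  })
  spec <- latent_class_spec(c(0.5, 0.5), ir)
  pr <- sample_indicator_profiles(spec, 20000, seed = 3)
  # plug-in mutual information between labels and an indicator
  mi <- function(a, b) {
    pj <- prop.table(table(a, b))
    pa <- rowSums(pj); pb <- colSums(pj)
    sum(ifelse(pj > 0, pj * log(pj / outer(pa, pb)), 0))
  }
  expect_lt(mi(pr$labels, pr$profiles$genspec_cat), 0.001)
  expect_lt(mi(pr$labels, pr$profiles$medication_cat), 0.001)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_patients = 60, n_distractors = 9, seed = 5)
  s1 <- simulate_claims(config = cfg, seed = 5)
  s2 <- simulate_claims(config = cfg, seed = 5)
  for (nm in names(s1$tables)) {
    expect_identical(s1$tables[[nm]], s2$tables[[nm]])
  }
  expect_identical(s1$labels, s2$labels)
})

test_that("invalid specifications are rejected", {
  lv <- indicator_levels()
  ir <- lapply(lv, function(vals) {
    m <- matrix(1 / length(vals), 2, length(vals)); m
  })
  expect_error(latent_class_spec(c(0.6, 0.6), ir), "sum")
  bad <- ir; bad$sex <- rbind(c(0.7, 0.4), c(0.5, 0.5))
  expect_error(latent_class_spec(c(0.5, 0.5), bad), "probability")
})

test_that("synthesised events respect the category bounds", {
  spec <- default_class_spec()
  pr <- sample_indicator_profiles(spec, 120, seed = 21)
  cfg <- simulation_config(n_patients = 120, seed = 21,
                           missing_prescription_region_share = 0)
  tables <- synthesize_claims(pr$profiles, pr$labels, cfg)
  codes <- cfg$codes
  iv <- tables$ed_visits[!duplicated(tables$ed_visits$patient_id), ]
  for (i in seq_len(nrow(pr$profiles))) {
    id <- sprintf("P%06d", i)
    idx_q <- quarter_of_date(min(tables$ed_visits$visit_date[
      tables$ed_visits$patient_id == id]))
    win <- lookback_quarters(idx_q, 4)
    be <- tables$billing_events
    hq <- unique(be$quarter[be$patient_id == id &
                              be$billing_code %in% codes$hba1c_codes])
    hc <- pr$profiles$hba1c_cat[i]
    if (hc == 0) expect_length(intersect(hq, win), 0)
    if (hc == 1) expect_true(length(intersect(hq, win)) %in% 1:2)
    if (hc == 2) expect_true(length(intersect(hq, win)) %in% 3:4)
    rx <- tables$prescriptions[tables$prescriptions$patient_id == id, ]
    ins <- any(startsWith(rx$atc_code, codes$insulin_atc_prefix))
    oad <- any(startsWith(rx$atc_code, codes$oad_atc_prefix))
    med <- pr$profiles$medication_cat[i]
    expect_equal(ins, med %in% c(2L, 3L))
    expect_equal(oad, med %in% c(1L, 3L))
  }
})

test_that("prescription removal matches the requested share", {
  cfg <- simulation_config(n_patients = 500, n_distractors = 0, seed = 8,
                           missing_prescription_region_share = 0)
  sim <- simulate_claims(config = cfg, seed = 8)
  t0 <- sim$tables
  expect_identical(inject_missing_prescriptions(t0, 0, seed = 1), t0)
  t1 <- inject_missing_prescriptions(t0, 1, seed = 1)
  expect_true(all(!t1$patients$rx_transmitted))
  expect_equal(nrow(t1$prescriptions), 0L)
  t2 <- inject_missing_prescriptions(t0, 0.204, seed = 1)
  share <- mean(!t2$patients$rx_transmitted)
  expect_gt(share, 0.14); expect_lt(share, 0.27)
  # prescriptions of unaffected patients are untouched
  keep <- t2$patients$patient_id[t2$patients$rx_transmitted]
  want <- t0$prescriptions[t0$prescriptions$patient_id %in% keep, , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(t2$prescriptions, want)
})

test_that("class-dependent outcomes target the published admission odds ratios", {
  spec <- default_class_spec()
  set.seed(2)
  lab <- sample.int(3, 100000, replace = TRUE, prob = spec$class_weights)
  out <- generate_outcomes(lab, spec, seed = 14)
  or_adm <- logistic_or(out$admitted, lab)$or
  expect_lt(abs(or_adm[1] - 1.27), 0.05)
  expect_lt(abs(or_adm[2] - 1.38), 0.05)
  # zero offsets: outcome independent of class
  spec0 <- spec
  spec0$outcome_log_odds$admitted$offsets <- c(0, 0, 0)
  out0 <- generate_outcomes(lab, spec0, seed = 15)
  or0 <- logistic_or(out0$admitted, lab)$or
  expect_lt(max(abs(or0 - 1)), 0.06)
  # degenerate intercept: no events at all
  specd <- spec
  specd$outcome_log_odds$recurrent_ed$intercept <- -Inf
  outd <- generate_outcomes(lab[1:1000], specd, seed = 16)
  expect_true(all(!outd$recurrent_ed))
})

test_that("claims tables survive a CSV round trip", {
  cfg <- simulation_config(n_patients = 40, n_distractors = 6, seed = 3)
  sim <- simulate_claims(config = cfg, seed = 3)
  dir <- withr::local_tempdir()
  write_claims_tables(sim$tables, dir)
  back <- read_claims_tables(dir)
  co1 <- build_cohort(sim$tables, cfg$codes)
  co2 <- build_cohort(back, cfg$codes)
  expect_equal(co1$members$patient_id, co2$members$patient_id)
  expect_equal(co1$attrition, co2$attrition)
})
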