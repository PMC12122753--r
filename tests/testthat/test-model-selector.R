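# Selection strategy: screen, split, elbow, silhouette, decision rule,
# partition agreement and stability.

test_that("the correlation screen flags redundant pairs and spares independent ones", {
  pr <- sample_indicator_profiles(default_class_spec(), 600, seed = 3)
  x <- pr$profiles
  x$creatinine_cat <- x$hba1c_cat  # perfect copy
  scr <- correlation_screen(x)
  expect_true(any(scr$flagged$correlation > 0.999))
  expect_true("creatinine_cat" %in% scr$dropped)
  # independent uniform columns: nothing flagged
  set.seed(5)
  y <- as.data.frame(lapply(indicator_levels(), function(v)
    sample(v, 10000, replace = TRUE)))
  scr2 <- correlation_screen(y)
  expect_equal(nrow(scr2$flagged), 0L)
  off <- scr2$correlation[upper.tri(scr2$correlation)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("the planted creatinine copy is dropped from the default generator", {
  pr <- sample_indicator_profiles(default_class_spec(), 4000, seed = 71)
  scr <- correlation_screen(pr$profiles)
  expect_equal(scr$dropped, "creatinine_cat")
  expect_length(scr$kept, 10)
  r <- scr$correlation["hba1c_cat", "creatinine_cat"]
  expect_gt(r, 0.5); expect_lt(r, 0.75)
})

test_that("the sample split is seeded, disjoint and exhaustive", {
  sp <- split_sample(10, 0.7, seed = 1)
  expect_length(sp$train, 7); expect_length(sp$validation, 3)
  expect_identical(split_sample(10, 0.7, seed = 1), sp)
  big <- split_sample(40561, 0.7, seed = 2)
  expect_length(intersect(big$train, big$validation), 0)
  expect_setequal(c(big$train, big$validation), seq_len(40561))
  expect_length(big$train, floor(0.7 * 40561))
  expect_error(split_sample(10, 1.2), "ratio")
})

test_that("the BIC elbow finds the kink", {
  # piecewise linear with a single kink at K = 3
  bic <- c(100, 70, 40, 38, 36, 34)
  expect_equal(bic_elbow(bic), 3)
  # hand-computed second differences: 25, 12, 2 -> K = 2
  expect_equal(bic_elbow(c(100, 60, 45, 42, 41)), 2)
  expect_warning(k <- bic_elbow(c(100, 90, 80, 70)), "degenerate")
  expect_equal(k, 2)
  expect_error(bic_elbow(c(2, 1)))
})

test_that("silhouette matches the brute-force oracle and its conventions", {
  # two clusters of duplicated rows, distinct between clusters
  x <- as.data.frame(matrix(c(rep(0L, 12), rep(1L, 12)), ncol = 3, byrow = FALSE))
  x <- data.frame(a = c(0, 0, 0, 1, 1, 1), b = c(0, 0, 0, 2, 2, 2),
                  c = c(1, 1, 1, 0, 0, 0))
  expect_equal(average_silhouette(x, c(1, 1, 1, 2, 2, 2)), 1)
  # six-point hand fixture with imperfect clusters
  y <- data.frame(a = c(0, 0, 1, 1, 1, 0), b = c(0, 1, 1, 1, 0, 0),
                  c = c(0, 0, 0, 1, 1, 1))
  cl <- c(1, 1, 1, 2, 2, 2)
  expect_equal(average_silhouette(y, cl), silhouette_brute(y, cl),
               tolerance = 1e-12)
  # random small fixtures against the oracle, including singletons
  for (s in 1:5) {
    set.seed(s)
    n <- sample(8:40, 1)
    z <- as.data.frame(matrix(sample(0:2, n * 4, replace = TRUE), n, 4))
    cz <- sample(1:3, n, replace = TRUE)
    if (length(unique(cz)) < 2) next
    expect_equal(average_silhouette(z, cz), silhouette_brute(z, cz),
                 tolerance = 1e-12)
    expect_lte(abs(average_silhouette(z, cz)), 1)
  }
  # random partition of i.i.d. rows scores near zero
  set.seed(7)
  w <- as.data.frame(matrix(sample(0:2, 2000 * 6, replace = TRUE), 2000, 6))
  cw <- sample(1:3, 2000, replace = TRUE)
  expect_lt(abs(average_silhouette(w, cw)), 0.05)
})

test_that("subsampled silhouette is seeded and bounded", {
  pr <- sample_indicator_profiles(default_class_spec(), 3000, seed = 9)
  m <- fit_lca(pr$profiles, 3, restarts = 4, seed = 2)
  map <- lca_posterior(m, pr$profiles)$map
  a1 <- average_silhouette(pr$profiles, map, subsample = 500, seed = 4)
  a2 <- average_silhouette(pr$profiles, map, subsample = 500, seed = 4)
  expect_identical(a1, a2)
  expect_lte(abs(a1), 1)
})

test_that("partition agreement matches exhaustive pair counting", {
  a <- c(1, 1, 1, 2); b <- c(1, 1, 2, 2)
  got <- compare_partitions(a, b)
  want <- pair_indices_brute(a, b)
  expect_equal(got$ari, want$ari, tolerance = 1e-12)
  expect_equal(got$jaccard, want$jaccard, tolerance = 1e-12)
  # identical and label-swapped partitions
  expect_equal(compare_partitions(b, b), list(ari = 1, jaccard = 1))
  expect_equal(compare_partitions(b, 3 - b), list(ari = 1, jaccard = 1))
  # symmetry and permutation invariance on random partitions
  for (s in 1:5) {
    set.seed(s)
    p <- sample(1:3, 30, replace = TRUE); q <- sample(1:4, 30, replace = TRUE)
    expect_equal(compare_partitions(p, q), compare_partitions(q, p))
    perm <- sample(4)
    expect_equal(compare_partitions(p, perm[q])$ari,
                 compare_partitions(p, q)$ari, tolerance = 1e-12)
    oracle <- pair_indices_brute(p, q)
    expect_equal(compare_partitions(p, q)$ari, oracle$ari, tolerance = 1e-12)
    expect_equal(compare_partitions(p, q)$jaccard, oracle$jaccard,
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with the mclust reference implementation", {
  set.seed(11)
  a <- sample(1:3, 200, replace = TRUE)
  b <- ifelse(stats::runif(200) < 0.8, a, sample(1:3, 200, replace = TRUE))
  expect_equal(compare_partitions(a, b)$ari,
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})

test_that("maximum-agreement matching recovers a label permutation", {
  set.seed(13)
  a <- sample(1:4, 100, replace = TRUE)
  perm <- c(3, 1, 4, 2)
  b <- perm[a]
  mp <- match_classes(a, b, K = 4)
  expect_equal(mp[b], a)
})

test_that("the selection rule follows majority, fallback and constraints", {
  mk <- function(bic, icl, asw, share, post) {
    data.frame(K = seq_along(bic), BIC = bic, ICL = icl,
               ASW = c(NA, asw[-1]), min_share = share,
               min_avg_posterior = post, converged = TRUE)
  }
  # all three criteria point to K = 3
  s1 <- mk(bic = c(100, 70, 40, 39, 38.5), icl = c(100, 72, 45, 50, 55),
           asw = c(NA, 0.2, 0.4, 0.3, 0.1), share = rep(0.2, 5),
           post = rep(0.9, 5))
  r1 <- select_model(s1)
  expect_equal(r1$chosen_k, 3L)
  expect_false(r1$failed)
  # criteria all disagree: max-ASW wins, trace says so
  s2 <- mk(bic = c(100, 60, 45, 42, 41), icl = c(90, 80, 70, 60, 50),
           asw = c(NA, 0.1, 0.35, 0.2, 0.15), share = rep(0.2, 5),
           post = rep(0.9, 5))
  r2 <- select_model(s2)
  expect_equal(r2$chosen_k, 3L)
  expect_true(any(grepl("no majority", r2$trace)))
  # majority K violates the share constraint; next candidate chosen
  s3 <- mk(bic = c(100, 70, 40, 39, 38.5), icl = c(100, 72, 45, 50, 55),
           asw = c(NA, 0.41, 0.4, 0.3, 0.1),
           share = c(1, 0.2, 0.03, 0.2, 0.2), post = rep(0.9, 5))
  r3 <- select_model(s3)
  expect_equal(r3$chosen_k, 2L)
  expect_true(any(grepl("violates|rejected", r3$trace)))
  # nothing satisfies the constraints
  s4 <- mk(bic = c(100, 70, 40, 39, 38.5), icl = c(100, 72, 45, 50, 55),
           asw = c(NA, 0.2, 0.4, 0.3, 0.1), share = rep(0.2, 5),
           post = rep(0.5, 5))
  r4 <- select_model(s4)
  expect_true(r4$failed)
  expect_true(is.na(r4$chosen_k))
})

test_that("bootstrap stability is high for structured data and low for noise", {
  spec <- make_test_spec(K = 3)
  pr <- sample_indicator_profiles(spec, 900, seed = 19)
  m <- fit_lca(pr$profiles, 3, restarts = 6, seed = 3)
  st <- bootstrap_stability(pr$profiles, m, B = 6, seed = 5, restarts = 4)
  expect_gte(st$mean_ari, 0.9)
  expect_gte(st$mean_jaccard, 0.85)
  expect_equal(nrow(st$per_resample), 6L)
  # pure-noise indicators forced into K = 3
  set.seed(23)
  noise <- as.data.frame(lapply(indicator_levels(), function(v)
    sample(v, 800, replace = TRUE)))
  mn <- fit_lca(noise, 3, restarts = 4, seed = 7)
  stn <- bootstrap_stability(noise, mn, B = 5, seed = 9, restarts = 3)
  expect_lt(stn$mean_ari, 0.2)
  # B = 0 gives an empty report without error
  st0 <- bootstrap_stability(pr$profiles, m, B = 0)
  expect_equal(st0$B, 0L)
  expect_equal(nrow(st0$per_resample), 0L)
})

test_that("holdout confirmation passes for same-generator validation data", {
  spec <- make_test_spec(K = 3)
  tr <- sample_indicator_profiles(spec, 900, seed = 31)
  va <- sample_indicator_profiles(spec, 500, seed = 32)
  m <- fit_lca(tr$profiles, 3, restarts = 6, seed = 4)
  hc <- holdout_confirmation(m, va$profiles, seed = 6, restarts = 6)
  expect_true(hc$pass)
  expect_gte(hc$ari, 0.9)
  expect_gte(hc$min_avg_posterior, 0.8)
  expect_error(holdout_confirmation(m, va$profiles[0, ]), "empty")
})
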