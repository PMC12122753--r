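# EM estimation of the categorical latent class model.

test_that("the one-class fit equals the independent-multinomial closed form", {
  pr <- sample_indicator_profiles(default_class_spec(), 400, seed = 5)
  m <- fit_lca(pr$profiles, 1, seed = 1)
  expect_equal(m$log_likelihood, loglik_k1_brute(pr$profiles), tolerance = 1e-10)
  expect_equal(m$pi, 1)
  expect_equal(m$entropy, 0)
  expect_equal(m$relative_entropy, 1)
  expect_equal(m$ICL, m$BIC)
  post <- lca_posterior(m, pr$profiles)
  expect_true(all(post$tau == 1))
  expect_true(all(post$map == 1L))
})

test_that("well-separated three-class parameters are recovered", {
  spec <- make_test_spec(K = 3)
  pr <- sample_indicator_profiles(spec, 3000, seed = 8)
  m <- fit_lca(pr$profiles, 3, restarts = 8, seed = 8, reorder = FALSE)
  post <- lca_posterior(m, pr$profiles)
  perm <- match_classes(pr$labels, post$map)
  expect_lt(max(abs(sort(m$pi) - sort(spec$class_weights))), 0.02)
  expect_gt(compare_partitions(pr$labels, post$map)$ari, 0.95)
  # matched item-response probabilities close to truth
  err <- max(vapply(names(spec$item_response), function(nm) {
    max(abs(t(m$theta[[nm]])[order(perm), ] - spec$item_response[[nm]]))
  }, numeric(1)))
  expect_lt(err, 0.05)
})

test_that("duplicating every row doubles the log-likelihood exactly", {
  pr <- sample_indicator_profiles(default_class_spec(), 300, seed = 17)
  x <- pr$profiles
  m1 <- fit_lca(x, 2, restarts = 4, seed = 6)
  m2 <- fit_lca(rbind(x, x), 2, restarts = 4, seed = 6)
  expect_equal(m2$log_likelihood, 2 * m1$log_likelihood, tolerance = 1e-6)
  expect_equal(m2$pi, m1$pi, tolerance = 1e-6)
  for (nm in names(m1$theta)) {
    expect_equal(m2$theta[[nm]], m1$theta[[nm]], tolerance = 1e-6)
  }
})

test_that("posteriors match the direct product-and-normalise oracle", {
  pr <- sample_indicator_profiles(default_class_spec(), 200, seed = 19)
  m <- fit_lca(pr$profiles, 3, restarts = 5, seed = 3)
  post <- lca_posterior(m, pr$profiles)
  expect_true(all(abs(rowSums(post$tau) - 1) < 1e-9))
  for (i in c(1, 37, 100)) {
    expect_equal(post$tau[i, ], posterior_brute(m, pr$profiles[i, ]),
                 tolerance = 1e-9)
  }
})

test_that("a mirrored two-class model gives an even posterior on a palindromic response", {
  lv <- indicator_levels()
  theta <- lapply(lv, function(vals) {
    C <- length(vals)
    p <- seq(0.2, 0.8, length.out = C); p <- p / sum(p)
    cbind(p, rev(p))
  })
  model <- structure(list(K = 2L, pi = c(0.5, 0.5), theta = theta,
                          levels = lv, columns = names(lv)),
                     class = "lca_model")
  # middle category of each indicator is the fixed point of the mirror
  row <- as.data.frame(lapply(lv, function(vals) vals[ceiling(length(vals) / 2)]))
  # only columns with odd category counts have an exact fixed point
  odd <- names(lv)[lengths(lv) %% 2 == 1]
  model$columns <- odd
  model$levels <- lv[odd]
  model$theta <- theta[odd]
  post <- lca_posterior(model, row[, odd, drop = FALSE])
  expect_equal(as.numeric(post$tau), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("entropy-based criteria match their definitions", {
  # hard one-hot posteriors
  tau_hard <- diag(3)[c(1, 2, 3, 1, 2), ]
  m_stub <- structure(list(K = 3L, BIC = 100), class = "lca_model")
  ic <- information_criteria(m_stub, tau_hard)
  expect_equal(ic$EN, 0); expect_equal(ic$E, 1); expect_equal(ic$ICL, ic$BIC)
  # maximally uncertain posteriors
  n <- 7
  tau_unif <- matrix(1 / 3, n, 3)
  ic2 <- information_criteria(m_stub, tau_unif)
  expect_equal(ic2$EN, n * log(3), tolerance = 1e-12)
  expect_equal(ic2$E, 0, tolerance = 1e-12)
  # generic fit: EN equals the brute-force double sum
  pr <- sample_indicator_profiles(default_class_spec(), 300, seed = 23)
  m <- fit_lca(pr$profiles, 3, restarts = 4, seed = 2)
  tau <- lca_posterior(m, pr$profiles)$tau
  en_brute <- -sum(apply(tau, 1, function(r) sum(ifelse(r > 0, r * log(r), 0))))
  expect_equal(information_criteria(m, tau)$EN, en_brute, tolerance = 1e-9)
  expect_equal(m$entropy, en_brute, tolerance = 1e-9)
  expect_gte(m$ICL, m$BIC)
})

test_that("discriminatory power is a mixture KL, zero for uninformative indicators", {
  lv <- indicator_levels()
  theta <- lapply(lv, function(vals) {
    C <- length(vals); matrix(1 / C, C, 2)
  })
  theta$sex <- cbind(c(0.9, 0.1), c(0.1, 0.9))
  model <- structure(list(K = 2L, pi = c(0.5, 0.5), theta = theta,
                          levels = lv, columns = names(lv)),
                     class = "lca_model")
  dp <- discriminatory_power(model)
  expect_equal(names(dp)[1], "sex")
  # closed form: marginal is (0.5, 0.5)
  kl <- 0.5 * (0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5)) * 2
  expect_equal(unname(dp["sex"]), kl, tolerance = 1e-12)
  expect_true(all(dp[names(dp) != "sex"] < 1e-12))
  # invariance to class relabelling
  model2 <- model
  model2$theta <- lapply(model$theta, function(m) m[, 2:1])
  expect_equal(sort(discriminatory_power(model2)), sort(dp), tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone and parameters stay normalised", {
  pr <- sample_indicator_profiles(default_class_spec(), 800, seed = 29)
  for (K in c(2, 4)) {
    m <- fit_lca(pr$profiles, K, restarts = 3, seed = 11)
    dll <- diff(m$ll_trace)
    expect_true(all(dll > -1e-7 * abs(m$log_likelihood)))
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    for (nm in names(m$theta)) {
      expect_true(all(abs(colSums(m$theta[[nm]]) - 1) < 1e-12))
      expect_true(all(m$theta[[nm]] >= 0 & m$theta[[nm]] <= 1))
    }
  }
})

test_that("fit statistics are invariant to class relabelling", {
  pr <- sample_indicator_profiles(default_class_spec(), 400, seed = 37)
  m1 <- fit_lca(pr$profiles, 3, restarts = 5, seed = 4, reorder = TRUE)
  m2 <- fit_lca(pr$profiles, 3, restarts = 5, seed = 4, reorder = FALSE)
  expect_equal(m1$log_likelihood, m2$log_likelihood)
  expect_equal(m1$BIC, m2$BIC)
  expect_equal(m1$entropy, m2$entropy, tolerance = 1e-9)
  expect_equal(m1$ICL, m2$ICL, tolerance = 1e-9)
  expect_setequal(round(m1$pi, 10), round(m2$pi, 10))
})

test_that("the best log-likelihood is non-decreasing in K", {
  pr <- sample_indicator_profiles(default_class_spec(), 1000, seed = 41)
  ll <- vapply(1:4, function(K) {
    fit_lca(pr$profiles, K, restarts = 15, tol = 1e-7, seed = 13)$log_likelihood
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-6 * abs(ll[1])))
})

test_that("canonical ordering puts the earliest disease stage first", {
  pr <- sample_indicator_profiles(default_class_spec(), 3000, seed = 43)
  m <- fit_lca(pr$profiles, 3, restarts = 8, seed = 9)
  stage <- vapply(1:3, function(k) {
    mean(c(0:3 %*% m$theta$medication_cat[, k],
           0:2 %*% m$theta$complication_cat[, k]))
  }, numeric(1))
  expect_true(!is.unsorted(stage))
})
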