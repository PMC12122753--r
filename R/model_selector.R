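# Extended model-selection strategy: local-independence screen, 1..Kmax
# grid of LCA fits, candidate classes from the BIC elbow / maximum ASW /
# minimum ICL, majority decision with class-share and posterior
# constraints, and partition-stability validation (bootstrap refits and a
# train/validation holdout) via ARI and Jaccard.

#' Local-independence screen
#'
#' Pairwise rank correlation (Spearman) on the ordinal category codes;
#' pairs at or above the threshold are flagged as local-independence
#' violations.  Within each flagged pair the default drop rule removes the
#' variable with the larger mean absolute correlation to all other
#' variables; profiles within `tie_tol` of each other are treated as tied
#' and the later column is dropped (a redundant copy of an earlier
#' variable carries an essentially identical correlation profile, so the
#' tie rule is what removes it deterministically).
#'
#' @param matrix completed indicator data frame (no missing cells).
#' @param threshold flagging threshold on `|r|` (default 0.50).
#' @param tie_tol tolerance under which two mean-absolute-correlation
#'   profiles count as tied.
#' @return list of class `correlation_screen`: `correlation` (matrix),
#'   `flagged` (data frame of flagged pairs), `dropped` (character),
#'   `kept` (character).
#' @export
correlation_screen <- function(matrix, threshold = 0.50, tie_tol = 0.02) {
  cols <- intersect(indicator_columns(), names(matrix))
  x <- as.data.frame(matrix)[, cols, drop = FALSE]
  assert_indicator_matrix(x, allow_missing = FALSE)
  r <- stats::cor(as.matrix(x), method = "spearman")
  up <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = cols[up[, 1]], var2 = cols[up[, 2]],
                        correlation = r[up], stringsAsFactors = FALSE)
  dropped <- character(0)
  if (nrow(flagged) > 0) {
    mean_abs <- function(v) mean(abs(r[v, setdiff(cols, v)]))
    for (i in seq_len(nrow(flagged))) {
      pair <- c(flagged$var1[i], flagged$var2[i])
      if (any(pair %in% dropped)) next
      ma <- vapply(pair, mean_abs, numeric(1))
      drop <- if (abs(ma[1] - ma[2]) <= tie_tol) {
        pair[which.max(match(pair, cols))]  # tie: later column order
      } else {
        pair[which.max(ma)]
      }
      dropped <- c(dropped, drop)
    }
  }
  structure(list(correlation = r, flagged = flagged, dropped = dropped,
                 kept = setdiff(cols, dropped), threshold = threshold),
            class = "correlation_screen")
}

#' Seeded train/validation split
#'
#' @param n number of rows.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with disjoint, exhaustive integer index vectors `train`
#'   (size `floor(ratio * n)`) and `validation`.
#' @export
split_sample <- function(n, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, n >= 2)
  set.seed(seed)
  train <- sort(sample.int(n, floor(ratio * n)))
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Average silhouette width under simple-matching distance
#'
#' Distance between two categorical profiles is the fraction of indicators
#' on which they disagree.  With this distance, mean distances from a
#' point to a cluster depend only on the cluster's per-category counts, so
#' the silhouette is computed exactly in `O(nJK)` without a distance
#' matrix.  Members of singleton clusters get `s(i) = 0` by convention.
#'
#' @param matrix categorical data frame.
#' @param clusters integer cluster assignment.
#' @param subsample if `n` exceeds this cap, a seeded subsample of this
#'   size is scored instead (default 10000).
#' @param seed seed for the subsample draw.
#' @return the average silhouette width (scalar in `[-1, 1]`).
#' @export
average_silhouette <- function(matrix, clusters, subsample = 10000L, seed = 1L) {
  x <- as.data.frame(matrix)
  if ("patient_id" %in% names(x)) x$patient_id <- NULL
  stopifnot(nrow(x) == length(clusters))
  keep_cl <- sort(unique(clusters))
  if (length(keep_cl) < 2L) stop("need at least two non-empty clusters")
  n_all <- nrow(x)
  idx <- seq_len(n_all)
  if (n_all > subsample) {
    set.seed(seed)
    idx <- sort(sample.int(n_all, subsample))
  }
  xs <- x[idx, , drop = FALSE]
  cl <- match(clusters[idx], keep_cl)
  K <- length(keep_cl); J <- ncol(xs); n <- nrow(xs)
  size <- tabulate(cl, nbins = K)
  # per column: category counts within each cluster, accumulated at each
  # row's own category -- mean simple-matching distances depend on nothing
  # else, so no pairwise distance matrix is needed
  match_sum <- matrix(0, n, K)  # sum over j of N_{C,j}(x_ij)
  for (j in seq_len(J)) {
    lev <- sort(unique(xs[[j]]))
    v <- match(xs[[j]], lev)
    tb <- table(factor(v, levels = seq_along(lev)),
                factor(cl, levels = seq_len(K)))
    counts <- matrix(as.integer(tb), length(lev), K)
    match_sum <- match_sum + counts[v, , drop = FALSE]
  }
  own_idx <- cbind(seq_len(n), cl)
  size_own <- size[cl]
  a <- (J * (size_own - 1L) - (match_sum[own_idx] - J)) /
    pmax(J * (size_own - 1L), 1L)
  m_other <- sweep(-match_sum, 2L, J * size, "+") /
    rep(pmax(J * size, 1L), each = n)
  m_other[own_idx] <- Inf
  m_other[, size == 0L] <- Inf
  b <- do.call(pmin, as.data.frame(m_other))
  s <- ifelse(size_own <= 1L, 0,
              ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b)))
  mean(s)
}

#' BIC elbow heuristic
#'
#' Locates the kink in the BIC-versus-K curve as the interior K maximising
#' the second difference `BIC(K-1) - 2 BIC(K) + BIC(K+1)`; ties break
#' towards the smaller K.  A strictly linear sequence is degenerate (all
#' second differences equal) and returns the smallest interior K with a
#' warning.
#'
#' @param bic numeric vector of BIC values for `K = 1, 2, ...`
#'   (length `>= 3`).
#' @return the elbow K (integer).
#' @export
bic_elbow <- function(bic) {
  stopifnot(length(bic) >= 3L)
  interior <- 2:(length(bic) - 1L)
  d2 <- bic[interior - 1L] - 2 * bic[interior] + bic[interior + 1L]
  if (length(d2) > 1L && diff(range(d2)) < 1e-9) {
    warning("BIC sequence has no curvature; elbow is degenerate")
  }
  interior[which.max(d2)]
}

#' Fit the 1..Kmax model grid
#'
#' Fits latent class models for every K, collecting fit and separation
#' criteria: BIC, ICL, entropy, scaled relative entropy, average
#' silhouette width of the MAP partition (K >= 2), smallest class share
#' and smallest class-average MAP posterior.
#'
#' @param matrix completed (screened) indicator data frame.
#' @param Kmax largest number of classes (default 10).
#' @param restarts,tol,max_iter passed to [fit_lca()].
#' @param seed master seed; per-K seeds are derived from it.
#' @param asw_subsample subsample cap for [average_silhouette()].
#' @return list of class `fit_summary` with `summary` (one row per K) and
#'   `models` (the fitted `lca_model` objects).
#' @export
fit_grid <- function(matrix, Kmax = 10L, restarts = 5L, tol = 1e-7,
                     max_iter = 500L, seed = 1L, asw_subsample = 10000L) {
  x <- as.data.frame(matrix)
  if ("patient_id" %in% names(x)) x$patient_id <- NULL
  models <- vector("list", Kmax)
  rows <- vector("list", Kmax)
  for (K in seq_len(Kmax)) {
    m <- fit_lca(x, K, restarts = restarts, tol = tol, max_iter = max_iter,
                 seed = derive_seed(seed, K))
    post <- lca_posterior(m, x)
    share <- tabulate(post$map, nbins = K) / nrow(x)
    avg_post <- vapply(seq_len(K), function(k) {
      rows_k <- post$map == k
      if (!any(rows_k)) return(NA_real_)
      mean(post$tau[rows_k, k])
    }, numeric(1))
    asw <- if (K >= 2L && length(unique(post$map)) >= 2L) {
      average_silhouette(x, post$map, subsample = asw_subsample,
                         seed = derive_seed(seed, 1000L + K))
    } else NA_real_
    models[[K]] <- m
    rows[[K]] <- data.frame(K = K, loglik = m$log_likelihood, BIC = m$BIC,
                            ICL = m$ICL, EN = m$entropy,
                            E = m$relative_entropy, ASW = asw,
                            min_share = min(share),
                            min_avg_posterior = min(avg_post, na.rm = TRUE),
                            converged = m$converged)
  }
  structure(list(summary = do.call(rbind, rows), models = models),
            class = "fit_summary")
}

#' Select the number of classes
#'
#' Candidates are the BIC-elbow K, the maximum-ASW K and the minimum-ICL
#' K.  The chosen K is the smallest candidate endorsed by at least two of
#' the three criteria; without a majority the maximum-ASW K is taken.
#' Constraints (smallest class share >= `min_share`, smallest
#' class-average MAP posterior >= `min_posterior`) are then checked; on
#' violation the next candidate by descending ASW is tried.  If no
#' candidate satisfies the constraints the report flags failure with the
#' chosen K unset.
#'
#' @param fit a `fit_summary` from [fit_grid()] (or its `summary` data
#'   frame).
#' @param min_share smallest admissible class share (default 0.05).
#' @param min_posterior smallest admissible class-average MAP posterior
#'   (default 0.80).
#' @return list of class `selection_report`: `candidates`, `chosen_k`,
#'   `constraints_ok`, `failed`, `trace` (character log of the decision).
#' @export
select_model <- function(fit, min_share = 0.05, min_posterior = 0.80) {
  s <- if (inherits(fit, "fit_summary")) fit$summary else fit
  stopifnot(all(c("K", "BIC", "ICL", "ASW", "min_share",
                  "min_avg_posterior") %in% names(s)))
  s <- s[order(s$K), , drop = FALSE]
  trace <- character(0)
  k_elbow <- bic_elbow(s$BIC)
  asw_ok <- which(!is.na(s$ASW))
  k_asw <- s$K[asw_ok[which.max(s$ASW[asw_ok])]]
  k_icl <- s$K[which.min(s$ICL)]
  cand <- c(elbow = k_elbow, asw = k_asw, icl = k_icl)
  trace <- c(trace, sprintf("candidates: BIC elbow K=%d, max ASW K=%d, min ICL K=%d",
                            k_elbow, k_asw, k_icl))
  votes <- table(cand)
  majority <- as.integer(names(votes)[votes >= 2])
  if (length(majority) > 0) {
    pick <- min(majority)
    trace <- c(trace, sprintf("majority of criteria endorse K=%d", pick))
  } else {
    pick <- k_asw
    trace <- c(trace, sprintf("no majority; falling back to max-ASW K=%d", pick))
  }
  constraint_ok <- function(K) {
    row <- s[s$K == K, ]
    row$min_share >= min_share && row$min_avg_posterior >= min_posterior
  }
  order_by_asw <- unique(c(pick, cand[order(-s$ASW[match(cand, s$K)])]))
  chosen <- NA_integer_
  ok <- FALSE
  for (K in order_by_asw) {
    if (constraint_ok(K)) {
      if (K != pick) {
        trace <- c(trace, sprintf("K=%d violates constraints; moving to K=%d",
                                  pick, K))
      } else {
        trace <- c(trace, sprintf("K=%d satisfies class-share >= %.2f and posterior >= %.2f",
                                  K, min_share, min_posterior))
      }
      chosen <- K; ok <- TRUE
      break
    } else {
      row <- s[s$K == K, ]
      trace <- c(trace, sprintf(
        "K=%d rejected: min share %.3f (limit %.2f), min avg posterior %.3f (limit %.2f)",
        K, row$min_share, min_share, row$min_avg_posterior, min_posterior))
    }
  }
  if (!ok) trace <- c(trace, "no candidate satisfies the constraints")
  structure(list(candidates = cand, chosen_k = chosen, constraints_ok = ok,
                 failed = !ok, trace = trace,
                 min_share = min_share, min_posterior = min_posterior),
            class = "selection_report")
}

#' Adjusted Rand index and Jaccard index of two partitions
#'
#' Pair-counting agreement: the ARI uses the standard
#' expectation-adjusted formula; the Jaccard index is
#' `n11 / (n11 + n10 + n01)` over co-assigned pairs.  Both are invariant
#' to label permutations.
#'
#' @param a,b integer assignment vectors of equal length.
#' @return list with `ari` and `jaccard`.
#' @export
compare_partitions <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  nij2 <- sum(choose(tab, 2))
  ai2 <- sum(choose(rowSums(tab), 2))
  bj2 <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- ai2 * bj2 / n2
  denom <- (ai2 + bj2) / 2 - expected
  ari <- if (denom == 0) 1 else (nij2 - expected) / denom
  n11 <- nij2
  n10 <- ai2 - nij2
  n01 <- bj2 - nij2
  jac <- if (n11 + n10 + n01 == 0) 1 else n11 / (n11 + n10 + n01)
  list(ari = ari, jaccard = jac)
}

#' Maximum-agreement class matching
#'
#' One-to-one matching of the labels of partition `b` onto partition `a`
#' maximising the total agreement over the K x K confusion matrix
#' (exhaustive over permutations for K <= 8, greedy beyond).
#'
#' @param a reference assignment; `b` assignment to be relabelled.
#' @param K number of classes.
#' @return integer vector `map` such that `map[b]` aligns with `a`.
#' @export
match_classes <- function(a, b, K = max(a, b)) {
  conf <- as.matrix(table(factor(b, levels = seq_len(K)),
                          factor(a, levels = seq_len(K))))
  if (K <= 8L) {
    perms <- permutations_of(K)
    agree <- vapply(seq_len(nrow(perms)), function(i) {
      sum(conf[cbind(seq_len(K), perms[i, ])])
    }, numeric(1))
    perms[which.max(agree), ]
  } else {
    map <- integer(K)
    cf <- conf
    for (z in seq_len(K)) {
      ij <- which(cf == max(cf), arr.ind = TRUE)[1, ]
      map[ij[1]] <- ij[2]
      cf[ij[1], ] <- -1; cf[, ij[2]] <- -1
    }
    map
  }
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                            sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE]))
  }
  dimnames(out) <- NULL
  out
}

#' Bootstrap partition stability
#'
#' For each resample: draw rows with replacement, refit a K-class model
#' with fresh restarts and a derived seed, MAP-classify the resampled
#' rows, and compare with the reference MAP assignment restricted to the
#' same rows (ARI and Jaccard are label-invariant, so no relabelling is
#' needed; the matched confusion is still computed for diagnostics).
#'
#' @param matrix completed indicator data frame the model was fitted on.
#' @param model the chosen `lca_model`.
#' @param B number of bootstrap resamples.
#' @param seed master seed.
#' @param restarts EM restarts per refit.
#' @return list of class `stability_report` with `mean_ari`,
#'   `mean_jaccard` and `per_resample`.
#' @export
bootstrap_stability <- function(matrix, model, B = 100L, seed = 1L,
                                restarts = 5L) {
  x <- as.data.frame(matrix)
  if ("patient_id" %in% names(x)) x$patient_id <- NULL
  if (B == 0L) {
    return(structure(list(type = "bootstrap", B = 0L, mean_ari = NA_real_,
                          mean_jaccard = NA_real_,
                          per_resample = data.frame(b = integer(),
                                                    ari = numeric(),
                                                    jaccard = numeric())),
                     class = "stability_report"))
  }
  ref_map <- lca_posterior(model, x)$map
  n <- nrow(x)
  res <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 5000L + b))
    idx <- sample.int(n, n, replace = TRUE)
    refit <- fit_lca(x[idx, , drop = FALSE], model$K, restarts = restarts,
                     tol = 1e-6, seed = derive_seed(seed, 6000L + b),
                     levels = model$levels, reorder = FALSE)
    new_map <- lca_posterior(refit, x[idx, , drop = FALSE])$map
    cp <- compare_partitions(ref_map[idx], new_map)
    res[[b]] <- data.frame(b = b, ari = cp$ari, jaccard = cp$jaccard)
  }
  per <- do.call(rbind, res)
  structure(list(type = "bootstrap", B = B, mean_ari = mean(per$ari),
                 mean_jaccard = mean(per$jaccard), per_resample = per),
            class = "stability_report")
}

#' Holdout confirmation of the chosen model
#'
#' Classifies the validation rows with the training model (E-step only),
#' refits a fresh K-class model on the validation data, and compares the
#' two partitions; additionally checks that the smallest class-average MAP
#' posterior of the training model on the validation data reaches the
#' accuracy target.
#'
#' @param model the chosen training `lca_model`.
#' @param validation completed indicator data frame (same category sets).
#' @param seed,restarts refit settings.
#' @param min_posterior accuracy target (default 0.80).
#' @return list of class `stability_report` with `ari`, `jaccard`,
#'   `min_avg_posterior` and the `pass` flag.
#' @export
holdout_confirmation <- function(model, validation, seed = 1L, restarts = 10L,
                                 min_posterior = 0.80) {
  x <- as.data.frame(validation)
  if ("patient_id" %in% names(x)) x$patient_id <- NULL
  if (nrow(x) == 0L) stop("validation set is empty")
  post <- lca_posterior(model, x)
  avg_post <- vapply(seq_len(model$K), function(k) {
    rows_k <- post$map == k
    if (!any(rows_k)) return(NA_real_)
    mean(post$tau[rows_k, k])
  }, numeric(1))
  refit <- fit_lca(x, model$K, restarts = restarts, tol = 1e-6,
                   seed = derive_seed(seed, 7000L), levels = model$levels,
                   reorder = FALSE)
  new_map <- lca_posterior(refit, x)$map
  cp <- compare_partitions(post$map, new_map)
  mp <- min(avg_post, na.rm = TRUE)
  structure(list(type = "holdout", ari = cp$ari, jaccard = cp$jaccard,
                 min_avg_posterior = mp, pass = mp >= min_posterior),
            class = "stability_report")
}
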