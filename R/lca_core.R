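# Latent class analysis for categorical indicators: maximum-likelihood
# estimation of a finite mixture of independent multinomials via EM.
# Duplicate response patterns are collapsed with multiplicity weights, so
# the E- and M-steps run over unique patterns; the likelihood is exact.

# encode a data frame of categorical columns as an integer pattern matrix
# (values are indices into the per-column level sets)
encode_categories <- function(data, levels = NULL) {
  data <- as.data.frame(data)
  if ("patient_id" %in% names(data)) data$patient_id <- NULL
  if (is.null(levels)) {
    levels <- lapply(data, function(v) sort(unique(v)))
  }
  stopifnot(all(names(data) %in% names(levels)) || is.null(names(levels)))
  if (is.null(names(levels))) names(levels) <- names(data)
  x <- matrix(0L, nrow(data), ncol(data),
              dimnames = list(NULL, names(data)))
  for (j in seq_along(data)) {
    idx <- match(data[[j]], levels[[names(data)[j]]])
    if (anyNA(idx)) {
      if (anyNA(data[[j]])) stop("missing cells present; impute first")
      stop(sprintf("column '%s' holds categories outside the model's levels",
                   names(data)[j]))
    }
    x[, j] <- idx
  }
  list(x = x, levels = levels[names(data)])
}

# collapse identical rows; returns unique patterns, weights, and row mapping
collapse_patterns <- function(x) {
  key <- do.call(paste, c(as.data.frame(x), sep = "\r"))
  first <- !duplicated(key)
  ux <- x[first, , drop = FALSE]
  id <- match(key, key[first])
  w <- tabulate(id, nbins = nrow(ux))
  list(x = ux, w = w, row_of = id)
}

# log joint density of every pattern under every class: P x K
pattern_loglik <- function(ux, log_theta, log_pi) {
  P <- nrow(ux); K <- length(log_pi)
  ll <- matrix(log_pi, P, K, byrow = TRUE)
  for (j in seq_len(ncol(ux))) {
    ll <- ll + log_theta[[j]][ux[, j], , drop = FALSE]
  }
  ll
}

row_logsumexp <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

PROB_FLOOR <- 1e-10

# M-step: weighted class responsibilities -> new parameters
m_step <- function(ux, tw, levels) {
  n_eff <- sum(tw)
  pi_new <- colSums(tw) / n_eff
  pi_new <- pmax(pi_new, PROB_FLOOR); pi_new <- pi_new / sum(pi_new)
  theta <- vector("list", ncol(ux))
  for (j in seq_len(ncol(ux))) {
    S <- rowsum(tw, group = ux[, j])
    full <- matrix(PROB_FLOOR, length(levels[[j]]), ncol(tw))
    full[as.integer(rownames(S)), ] <- pmax(S, PROB_FLOOR)
    theta[[j]] <- sweep(full, 2L, colSums(full), "/")
  }
  names(theta) <- names(levels)
  list(pi = pi_new, theta = theta)
}

em_run <- function(ux, w, levels, K, tol, max_iter, init_seed) {
  set.seed(init_seed)
  P <- nrow(ux); n <- sum(w)
  tau <- matrix(stats::runif(P * K), P, K)
  tau <- tau / rowSums(tau)
  par <- m_step(ux, tau * w, levels)
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lt <- lapply(par$theta, log)
    lj <- pattern_loglik(ux, lt, log(par$pi))
    lse <- row_logsumexp(lj)
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    tau <- exp(lj - lse)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    par <- m_step(ux, tau * w, levels)
    ll_prev <- ll
  }
  list(pi = par$pi, theta = par$theta, ll = trace[length(trace)],
       trace = trace, converged = converged, n_iter = it, tau = tau)
}

#' Fit a latent class model
#'
#' EM from `restarts` random-responsibility initialisations; the fit with
#' the best log-likelihood is kept (ties broken by lower restart index).
#' The E-step runs in log space; the M-step applies a probability floor of
#' `1e-10` followed by renormalisation to guard against log-domain
#' underflow on empty cells.  With `K = 1` the maximum-likelihood solution
#' (independent multinomial marginals) is computed in closed form.
#'
#' Classes are reported in a canonical order: ascending disease-stage score
#' (mean expected category code of the medication and complication
#' indicators), so class 1 is the earliest-stage class whenever those two
#' indicators are present.
#'
#' @param data data frame of categorical indicators without missing cells
#'   (a `patient_id` column, if present, is ignored).
#' @param K number of classes, `>= 1`.
#' @param restarts number of random EM restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param seed master seed; restart `r` uses a seed derived from it.
#' @param levels optional named list fixing the category sets (needed when
#'   a data subset might not exhibit every category).
#' @param reorder apply the canonical class ordering (default `TRUE`).
#' @return object of class `lca_model`: mixture weights `pi`, item
#'   response probabilities `theta` (per indicator a `C_j x K` matrix),
#'   `log_likelihood`, `ll_trace`, `n_params`, `BIC`, `entropy`,
#'   `relative_entropy`, `ICL`, `converged`, `n_iter`, `best_restart`,
#'   plus the category `levels` and column order.
#' @export
fit_lca <- function(data, K, restarts = 20L, tol = 1e-8, max_iter = 500L,
                    seed = 1L, levels = NULL, reorder = TRUE) {
  enc <- encode_categories(data, levels)
  n <- nrow(enc$x)
  stopifnot(K >= 1L, n > K)
  cp <- collapse_patterns(enc$x)
  if (K > nrow(cp$x)) {
    warning(sprintf("K = %d exceeds the %d distinct response patterns",
                    K, nrow(cp$x)))
  }
  Cj <- lengths(enc$levels)

  if (K == 1L) {
    theta <- vector("list", ncol(enc$x))
    ll <- 0
    for (j in seq_len(ncol(enc$x))) {
      cnt <- tabulate(enc$x[, j], nbins = Cj[j])
      ll <- ll + sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
      theta[[j]] <- matrix(pmax(cnt / n, PROB_FLOOR), Cj[j], 1L)
      theta[[j]] <- theta[[j]] / sum(theta[[j]])
    }
    names(theta) <- names(enc$levels)
    best <- list(pi = 1, theta = theta, ll = ll, trace = ll, converged = TRUE,
                 n_iter = 0L, tau = matrix(1, nrow(cp$x), 1L))
    best_r <- 0L
  } else {
    best <- NULL; best_r <- NA_integer_
    for (r in seq_len(restarts)) {
      run <- em_run(cp$x, cp$w, enc$levels, K, tol, max_iter,
                    init_seed = derive_seed(seed, r))
      if (is.null(best) || run$ll > best$ll) {
        best <- run; best_r <- r
      }
    }
    if (!is.finite(best$ll)) stop("non-finite likelihood in every restart")
  }

  ord <- seq_len(K)
  if (reorder && K > 1L &&
      all(c("medication_cat", "complication_cat") %in% names(enc$levels))) {
    stage <- function(nm) {
      codes <- indicator_levels()[[nm]]
      as.numeric(codes %*% best$theta[[nm]])
    }
    sc <- (stage("medication_cat") + stage("complication_cat")) / 2
    ord <- order(sc)
  }
  pi_ <- best$pi[ord]
  theta <- lapply(best$theta, function(m) m[, ord, drop = FALSE])
  tau_p <- best$tau[, ord, drop = FALSE]

  p <- (K - 1L) + K * sum(Cj - 1L)
  bic <- -2 * best$ll + p * log(n)
  tau_rows <- tau_p[cp$row_of, , drop = FALSE]
  en <- entropy_of(tau_rows)
  e_rel <- if (K >= 2L) 1 - en / (n * log(K)) else 1
  structure(list(K = K, n = n, pi = pi_, theta = theta,
                 log_likelihood = best$ll, ll_trace = best$trace,
                 n_params = p, BIC = bic, entropy = en,
                 relative_entropy = e_rel, ICL = bic + 2 * en,
                 converged = best$converged, n_iter = best$n_iter,
                 best_restart = best_r, seed = seed,
                 levels = enc$levels, columns = colnames(enc$x)),
            class = "lca_model")
}

entropy_of <- function(tau) {
  v <- tau * log(tau)
  v[!is.finite(v)] <- 0
  -sum(v)
}

#' Posterior class memberships
#'
#' `tau[i, k]` is proportional to `pi_k * prod_j theta[k, j, x_ij]`,
#' normalised per row and computed in log space.  The MAP assignment
#' breaks ties deterministically towards the lowest class index.
#'
#' @param model a fitted [fit_lca()] model.
#' @param data data frame with the model's indicator columns, no missing
#'   cells.
#' @return list with `tau` (n x K matrix) and `map` (integer vector).
#' @export
lca_posterior <- function(model, data) {
  enc <- encode_categories(as.data.frame(data)[, model$columns, drop = FALSE],
                           model$levels)
  lj <- pattern_loglik(enc$x, lapply(model$theta, log), log(model$pi))
  lse <- row_logsumexp(lj)
  tau <- exp(lj - lse)
  map <- max.col(tau, ties.method = "first")
  list(tau = tau, map = map)
}

#' Fit and separation criteria from posteriors
#'
#' `EN = -sum_i sum_k tau_ik log tau_ik` (with `0 log 0 = 0`), scaled
#' relative entropy `E = 1 - EN / (n log K)` (1 for `K = 1`), and
#' `ICL = BIC + 2 EN`.
#'
#' @param model a fitted [fit_lca()] model.
#' @param tau posterior matrix consistent with the model (defaults to the
#'   training posteriors are not stored, so pass the output of
#'   [lca_posterior()]).
#' @return list with `BIC`, `EN`, `E`, `ICL`.
#' @export
information_criteria <- function(model, tau) {
  en <- entropy_of(tau)
  n <- nrow(tau)
  e_rel <- if (model$K >= 2L) 1 - en / (n * log(model$K)) else 1
  list(BIC = model$BIC, EN = en, E = e_rel, ICL = model$BIC + 2 * en)
}

#' Rank indicators by discriminatory power
#'
#' Default metric: the mixture-weighted Kullback-Leibler divergence of each
#' indicator's class-conditional distribution from its mixture marginal,
#' `sum_k pi_k KL(theta_kj || theta_bar_j)`.  An indicator identical
#' across classes scores 0; scores are invariant to class relabelling.
#'
#' @param model a fitted [fit_lca()] model.
#' @param score_fn optional replacement metric `function(theta_j, pi)`.
#' @return named numeric vector, sorted descending.
#' @export
discriminatory_power <- function(model, score_fn = NULL) {
  if (is.null(score_fn)) {
    score_fn <- function(theta_j, pi) {
      marg <- as.numeric(theta_j %*% pi)
      sum(vapply(seq_along(pi), function(k) {
        p <- theta_j[, k]
        pi[k] * sum(ifelse(p > 0, p * log(p / marg), 0))
      }, numeric(1)))
    }
  }
  scores <- vapply(model$theta, score_fn, numeric(1), pi = model$pi)
  sort(scores, decreasing = TRUE)
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("Latent class model: K = %d, n = %d, logLik = %.2f, BIC = %.2f\n",
              x$K, x$n, x$log_likelihood, x$BIC))
  cat("class weights:", paste(signif(x$pi, 4), collapse = " "), "\n")
  cat(sprintf("entropy = %.2f, relative entropy = %.3f, ICL = %.2f, %s\n",
              x$entropy, x$relative_entropy, x$ICL,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  invisible(x)
}
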