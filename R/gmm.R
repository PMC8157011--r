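#' Fit a Gaussian mixture model with full covariances
#'
#' EM with one fully parameterised covariance matrix per component
#' (ridge-regularised on the diagonal), means initialised by k-means per
#' restart, `n_init` restarts with deterministically derived seeds; the
#' restart with the highest final log-likelihood wins. Restarts that
#' produce an empty component are re-initialised (counted in
#' `n_reinit`).
#'
#' @param latent numeric matrix, samples in rows (the cluster latent
#'   space).
#' @param K number of mixture components; must be `< nrow(latent)`.
#' @param n_init number of restarts (default 50).
#' @param seed integer seed; restart `r` uses `seed + r`.
#' @param ridge diagonal regularisation factor relative to each
#'   component's mean diagonal covariance (default 1e-6).
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return A `milk_gmm`: `weights`, `means` (K x d), `covariances`
#'   (d x d x K), `loglik`, per-iteration `loglik_trace` of the winning
#'   restart, hard training `labels`, `n_reinit`.
#' @export
fit_gmm <- function(latent, K, n_init = 50L, seed = 1L, ridge = 1e-6,
                    max_iter = 200L, tol = 1e-8) {
  X <- as.matrix(latent)
  n <- nrow(X)
  if (n <= K) stop("fit error: need n > K (n = ", n, ", K = ", K, ")")
  best <- NULL
  n_reinit <- 0L
  for (r in seq_len(n_init)) {
    attempt <- 0L
    fit <- NULL
    while (is.null(fit) && attempt < 5L) {
      fit <- tryCatch(
        em_gmm(X, K, seed = seed + r + 7919L * attempt,
               ridge = ridge, max_iter = max_iter, tol = tol),
        empty_component = function(e) NULL
      )
      if (is.null(fit)) n_reinit <- n_reinit + 1L
      attempt <- attempt + 1L
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("fit error: all GMM restarts degenerated")
  best$n_reinit <- n_reinit
  best$K <- as.integer(K)
  best$d <- ncol(X)
  class(best) <- "milk_gmm"
  best
}

em_gmm <- function(X, K, seed, ridge, max_iter, tol) {
  n <- nrow(X)
  d <- ncol(X)
  init_labels <- with_seed(seed, kmeans_labels(X, K))
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), init_labels)] <- 1
  weights <- numeric(K)
  means <- matrix(0, K, d)
  covs <- array(0, c(d, d, K))
  total_scale <- mean(apply(X, 2L, stats::var))
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter + 1L)) {
    # M-step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {
      cond <- structure(class = c("empty_component", "condition"),
                        list(message = "empty component during EM",
                             call = NULL))
      stop(cond)
    }
    weights <- nk / n
    for (k in seq_len(K)) {
      mu <- colSums(resp[, k] * X) / nk[k]
      means[k, ] <- mu
      Xc <- sweep(X, 2L, mu)
      S <- crossprod(sqrt(resp[, k]) * Xc) / nk[k]
      rdg <- ridge * max(mean(diag(S)), 1e-10 * total_scale, 1e-300)
      covs[, , k] <- S + diag(rdg, d)
    }
    # E-step
    logdens <- matrix(0, n, K)
    for (k in seq_len(K)) {
      logdens[, k] <- log(weights[k]) +
        dmvnorm_log(X, means[k, ], covs[, , k])
    }
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logdens - lse)
    if (is.finite(ll_old) && (ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = weights, means = means, covariances = covs,
       loglik = ll, loglik_trace = loglik_trace,
       labels = max.col(resp, ties.method = "first"),
       n_iter = length(loglik_trace))
}

kmeans_labels <- function(X, K) {
  n <- nrow(X)
  if (n == K) return(seq_len(n))
  for (try in 1:10) {
    km <- tryCatch(
      stats::kmeans(X, centers = K, iter.max = 10L, nstart = 1L),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(km) && length(unique(km$cluster)) == K) return(km$cluster)
  }
  # fall back to random balanced labels
  sample(rep_len(seq_len(K), n))
}

dmvnorm_log <- function(X, mu, sigma) {
  d <- length(mu)
  ch <- chol(sigma)
  z <- backsolve(ch, t(sweep(X, 2L, mu)), transpose = TRUE)
  -0.5 * (d * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Mixture log-density and component posteriors for new data
#'
#' @param gmm a `milk_gmm`.
#' @param X latent matrix, samples in rows.
#' @return `gmm_log_density`: total mixture log-density per sample.
#'   `predict_gmm`: hard component labels (posterior argmax).
#' @export
gmm_log_density <- function(gmm, X) {
  X <- as.matrix(X)
  logdens <- vapply(seq_len(gmm$K), function(k) {
    log(gmm$weights[k]) + dmvnorm_log(X, gmm$means[k, ], gmm$covariances[, , k])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logdens <- matrix(logdens, nrow = 1L)
  m <- apply(logdens, 1L, max)
  m + log(rowSums(exp(logdens - m)))
}

#' @rdname gmm_log_density
#' @export
predict_gmm <- function(gmm, X) {
  X <- as.matrix(X)
  logdens <- vapply(seq_len(gmm$K), function(k) {
    log(gmm$weights[k]) + dmvnorm_log(X, gmm$means[k, ], gmm$covariances[, , k])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logdens <- matrix(logdens, nrow = 1L)
  max.col(logdens, ties.method = "first")
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# mean silhouette width over all samples (Euclidean distance);
# singleton clusters get width 0 by convention
silhouette_mean <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(unique(labels)) < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
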