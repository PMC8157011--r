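test_that("single-component GMM equals the closed-form Gaussian fit", {
  set.seed(2)
  X <- matrix(rnorm(200L * 3L), 200L)
  g <- fit_gmm(X, K = 1L, n_init = 1L, seed = 1L)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2L, mu)) / nrow(X)
  S <- S + diag(1e-6 * mean(diag(S)), 3L)  # same pinned ridge
  expect_equal(drop(g$means), mu, tolerance = 1e-10)
  expect_equal(g$covariances[, , 1L], S, tolerance = 1e-10)
  ch <- chol(S)
  z <- backsolve(ch, t(sweep(X, 2L, mu)), transpose = TRUE)
  ll <- -0.5 * nrow(X) * (3 * log(2 * pi)) - nrow(X) * sum(log(diag(ch))) -
    0.5 * sum(z^2)
  expect_equal(g$loglik, ll, tolerance = 1e-8)
})

test_that("two planted blobs are recovered exactly", {
  b <- blob_latent(n_per = 40L, k = 2L, d = 5L, sep = 10, seed = 3L)
  g <- fit_gmm(b$X, K = 2L, n_init = 5L, seed = 1L)
  expect_equal(adjusted_rand_index(g$labels, b$labels), 1.0)
})

test_that("EM log-likelihood is monotone and best-of-restarts dominates", {
  b <- blob_latent(n_per = 20L, k = 4L, d = 6L, sep = 6, seed = 4L)
  singles <- vapply(1:5, function(r) {
    fit_gmm(b$X, K = 4L, n_init = 1L, seed = r + 100L)$loglik
  }, numeric(1L))
  best <- fit_gmm(b$X, K = 4L, n_init = 5L, seed = 100L)
  expect_gte(best$loglik + 1e-8, max(singles))
  expect_true(all(diff(best$loglik_trace) > -1e-6 * abs(best$loglik)))
  expect_error(fit_gmm(b$X[1:3, ], K = 4L), "fit error")
})

test_that("cluster latent space reaches its variance target and inverts", {
  fx <- study_small()
  expect_gte(fx$latent_fit$explained_variance, 0.995)
  expect_equal(fx$latent_fit$n_components, 24L)
  # robust-scaled training data have per-point median 0, IQR 1
  Xs <- as_matrix(apply_scaler(fx$atyp, fx$latent_fit$scaler))
  expect_lt(max(abs(apply(Xs, 2L, median))), 1e-10)
  # projection of an in-span point inverts exactly
  pca <- fx$latent_fit$pca
  x <- pca$center + drop(pca$rotation %*% rnorm(24L))
  lat <- pca_project(matrix(x, 1L), pca)
  expect_equal(drop(pca_reconstruct(lat, pca)), x, tolerance = 1e-10)
  expect_error(fit_cluster_latent(fx$atyp[1:10]), "fit error")
})

test_that("K sweep covers the range and silhouette peaks near truth", {
  b <- blob_latent(n_per = 15L, k = 10L, d = 24L, sep = 12, seed = 5L)
  sw <- sweep_k(b$X, k_min = 4L, k_max = 20L, n_init = 3L, seed = 2L)
  expect_length(sw, 17L)
  ok <- !vapply(sw, function(e) is.null(e$gmm), logical(1L))
  expect_true(all(vapply(sw[ok], function(e) {
    sum(e$diagnostics$sizes) == nrow(b$X)
  }, logical(1L))))
  sil <- vapply(sw, function(e) {
    if (is.null(e$gmm)) -Inf else e$diagnostics$silhouette
  }, numeric(1L))
  best_k <- sw[[which.max(sil)]]$K
  expect_gte(best_k, 8L)
  expect_lte(best_k, 12L)
})

test_that("cluster diagnostics cover the six evaluation criteria", {
  fx <- study_small()
  d <- evaluate_clusters(fx$gmm$labels, fx$atyp, fx$latent)
  expect_equal(sum(d$sizes$size), n_samples(fx$atyp))
  expect_true(all(d$within_between$ratio[!d$within_between$degenerate] > 0))
  expect_true(all(d$farms$unique_farm_pct >= 0 &
                    d$farms$unique_farm_pct <= 100))
  expect_true(all(d$temporal$concentration_14d <= 1))
  expect_setequal(unique(d$composition$analyte), analyte_columns())

  # the planted fringe cluster is instrument-pure up to two exceptions
  fringe_cl <- d$instruments$cluster[which.min(d$instruments$entropy)]
  members <- fx$truth[fx$gmm$labels == fringe_cl]
  expect_gt(mean(members == "INSTRUMENT_FRINGE"), 0.9)
  inst <- fx$atyp$meta$instrument_id[fx$gmm$labels == fringe_cl]
  expect_lte(length(inst) - max(table(inst)), 2L)

  # degenerate case: a single cluster has no between-distance
  d1 <- evaluate_clusters(rep(1L, n_samples(fx$atyp)), fx$atyp, fx$latent)
  expect_true(d1$within_between$degenerate)
})

test_that("printed-count example: 529 spectra from 227 farms give 42.9%", {
  labels <- rep(1L, 529L)
  farms <- c(sprintf("F%03d", 1:227),
             sample(sprintf("F%03d", 1:227), 302L, replace = TRUE))
  d <- evaluate_clusters(labels,
                         spectrum_set(matrix(0, 529L, 3L),
                                      within(meta_stub(529L),
                                             farm_id <- farms),
                                      c(3, 2, 1)))
  expect_equal(round(d$farms$unique_farm_pct, 1L), 42.9)
})

test_that("merge maps follow union-find with size-ordered relabelling", {
  g <- list(K = 11L, labels = rep(1:11, times = c(30, 25, 20, 15, 14, 12,
                                                  10, 8, 6, 5, 4)))
  mm <- merge_clusters(g, list(c(10L, 11L)))
  expect_equal(max(mm), 10L)
  expect_equal(mm[10L], mm[11L])
  # merged 10+11 has 9 members -> outranks cluster 9 (6) and 8 (8)
  expect_lt(mm[10L], mm[9L])

  expect_equal(merge_clusters(g, list()), 1:11)
  chain <- merge_clusters(g, list(c(1L, 2L), c(2L, 3L)))
  expect_equal(length(unique(chain[1:3])), 1L)
  expect_error(merge_clusters(g, list(c(1L, 99L))), "argument error")
})

test_that("instrument-split clusters are proposed for merging", {
  # two composition-identical clusters split 2+2 across instruments
  n <- 40L
  meta <- meta_stub(2L * n)
  meta$instrument_id <- c(rep(c("I1", "I2"), n / 2),
                          rep(c("I3", "I4"), n / 2))
  meta$fat <- rnorm(2L * n, 4.4, 0.1)
  labels <- rep(c(1L, 2L), each = n)
  set <- spectrum_set(matrix(rnorm(2L * n * 3L), 2L * n), meta, c(3, 2, 1))
  d <- evaluate_clusters(labels, set)
  expect_equal(suggest_instrument_merges(d), list(c(1L, 2L)))

  # identical instrument mixes: no proposal
  meta2 <- meta
  meta2$instrument_id <- rep(c("I1", "I2", "I3", "I4"), n / 2)
  d2 <- evaluate_clusters(labels, spectrum_set(set$absorbance, meta2,
                                               set$grid))
  expect_equal(suggest_instrument_merges(d2), list())

  d3 <- evaluate_clusters(rep(1L, 2L * n), set)
  expect_equal(suggest_instrument_merges(d3), list())
})

test_that("diagnostics are invariant under row permutation", {
  fx <- study_small()
  perm <- sample(n_samples(fx$atyp))
  d1 <- evaluate_clusters(fx$gmm$labels, fx$atyp, fx$latent)
  d2 <- evaluate_clusters(fx$gmm$labels[perm], fx$atyp[perm],
                          fx$latent[perm, ])
  expect_equal(d2$sizes, d1$sizes)
  expect_equal(d2$farms, d1$farms)
  expect_equal(d2$within_between, d1$within_between)
  expect_equal(d2$composition, d1$composition)
})
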