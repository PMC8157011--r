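test_that("freezing-point filter drops the strict percentile tails", {
  set <- typical_small()
  big <- screen_fixture()$raw
  surv <- filter_freezing_point(big)
  # oracle: count values within the inverse-ECDF percentile bounds
  fp <- big$meta$freezing_point
  qs <- quantile(fp, c(0.01, 0.99), names = FALSE, type = 1)
  expect_equal(n_samples(surv), sum(fp >= qs[1L] & fp <= qs[2L]))
  expect_gte(n_samples(surv), 978L)
  expect_lte(n_samples(surv), 982L)
  expect_identical(surv$meta$sample_id,
                   big$meta$sample_id[fp >= qs[1L] & fp <= qs[2L]])

  flat <- set[1:10]
  flat$meta$freezing_point <- -0.52
  expect_equal(n_samples(filter_freezing_point(flat)), 10L)
  expect_equal(n_samples(filter_freezing_point(set[1:2])), 2L)

  bad <- set[1:5]
  bad$meta$freezing_point[2L] <- NA
  expect_error(filter_freezing_point(bad), "data error")
})

test_that("Mahalanobis distance matches identities and a dense oracle", {
  fx <- screen_fixture()
  m <- fx$model
  expect_equal(mahalanobis_distance(m$latent_mean, m), 0)

  ident <- m
  ident$latent_precision <- diag(16L)
  x <- m$latent_mean
  x[1:2] <- x[1:2] + c(3, 4)
  expect_equal(mahalanobis_distance(x, ident), 5)

  set.seed(8)
  L <- matrix(rnorm(50L * 16L), 50L)
  d <- mahalanobis_distance(L, m)
  # oracle: explicit dense inverse of the latent covariance (+ridge)
  P <- solve(m$latent_covariance)
  oracle <- vapply(seq_len(50L), function(i) {
    v <- L[i, ] - m$latent_mean
    sqrt(drop(t(v) %*% P %*% v))
  }, numeric(1L))
  expect_equal(d, oracle, tolerance = 1e-8)

  expect_error(mahalanobis_distance(c(NA, rep(0, 15L)), m), "data error")
  expect_error(mahalanobis_distance(rep(0, 5L), m), "shape error")
})

test_that("reconstruction residual matches the explicit projection oracle", {
  fx <- screen_fixture()
  m <- fx$model
  p <- length(m$scaler$center)
  expect_equal(reconstruction_residual(rep(0, p), m), 0)

  in_span <- drop(m$pca$rotation %*% rnorm(16L))
  expect_lt(reconstruction_residual(in_span, m), 1e-10)

  set.seed(9)
  X <- matrix(rnorm(20L * p), 20L)
  r <- reconstruction_residual(X, m)
  B <- m$pca$rotation
  oracle <- sqrt(rowMeans((X - X %*% B %*% t(B))^2))
  expect_equal(r, oracle, tolerance = 1e-10)
})

test_that("anomaly scores are centred on training and decompose exactly", {
  fx <- screen_fixture()
  res <- anomaly_scores(fx$pp, fx$model)
  expect_lt(abs(mean(res$anomaly_score)), 0.05)
  # decomposition: score equals the sum of its two frozen z-scores
  z <- (res$mahalanobis - fx$model$maha_std[["mean"]]) /
    fx$model$maha_std[["sd"]] +
    (res$residual_rmse - fx$model$resid_std[["mean"]]) /
    fx$model$resid_std[["sd"]]
  expect_equal(res$anomaly_score, z, tolerance = 1e-12)

  dup <- fx$pp[c(1L, 1L)]
  sdup <- anomaly_scores(dup, fx$model)
  expect_equal(sdup$anomaly_score[1L], sdup$anomaly_score[2L],
               tolerance = 1e-12)
})

test_that("a strong fringe ripple scores beyond the training tail", {
  fx <- screen_fixture()
  res <- anomaly_scores(fx$pp, fx$model)
  spiked <- fx$raw[1:5]
  ripple <- 10 * 50 * tiny_config()$noise_sd *
    sin(2 * pi * spiked$grid / 100)
  spiked$absorbance <- sweep(spiked$absorbance, 2L, ripple, "+")
  sp <- anomaly_scores(preprocess_spectra(spiked), fx$model)
  expect_true(all(sp$anomaly_score >
                    quantile(res$anomaly_score, 0.999, type = 7)))
})

test_that("Mahalanobis term grows along eigenvector directions", {
  fx <- screen_fixture()
  m <- fx$model
  ev <- eigen(m$latent_covariance, symmetric = TRUE)$vectors
  for (j in c(1L, 8L, 16L)) {
    d <- vapply(c(0, 0.5, 1, 2, 5), function(a) {
      mahalanobis_distance(m$latent_mean + a * ev[, j], m)
    }, numeric(1L))
    expect_true(all(diff(d) > 0))
  }
})

test_that("trim iterations follow the ceil arithmetic exactly", {
  fx <- screen_fixture()
  expect_identical(fx$model$trim_history, c(1L, 1L))
  expect_identical(fx$model$n_train_final, 998L)
  expect_gte(fx$model$explained_variance, 0.95)

  no_trim <- fit_screening_model(fx$pp[1:200], trim_fraction = 0)
  expect_identical(no_trim$trim_history, integer(0))
  expect_identical(no_trim$n_train_final, 200L)

  expect_error(fit_screening_model(fx$pp[1:10]), "fit error")
})

test_that("monthly flagging applies the floor rule with stable ties", {
  mk <- function(n, month) {
    data.frame(sample_id = sprintf("%s-%04d", month, seq_len(n)),
               anomaly_score = seq_len(n) / n, month = month,
               flagged = NA)
  }
  res <- flag_monthly(rbind(mk(2000L, "2018-01"), mk(400L, "2018-02")),
                      0.001)
  jan <- res[res$month == "2018-01", ]
  expect_equal(sum(jan$flagged), 2L)
  expect_setequal(jan$sample_id[jan$flagged],
                  c("2018-01-2000", "2018-01-1999"))
  expect_equal(sum(res$flagged[res$month == "2018-02"]), 0L)

  # equal-size months flag equal counts; ties broken by sample_id
  tied <- rbind(mk(1000L, "2018-03"), mk(1000L, "2018-04"))
  tied$anomaly_score <- 1
  out <- flag_monthly(tied, 0.002)
  counts <- tapply(out$flagged, out$month, sum)
  expect_true(all(counts == 2L))
  expect_setequal(out$sample_id[out$flagged & out$month == "2018-03"],
                  c("2018-03-0001", "2018-03-0002"))
})
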