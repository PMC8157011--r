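#' Freezing-point percentile filter
#'
#' Removes samples whose milk freezing point lies strictly below the
#' `lower_pct` or strictly above the `upper_pct` percentile of the input
#' distribution. Percentiles use the inverse empirical CDF (quantile
#' type 1), so degenerate inputs (two samples, or all values equal)
#' survive intact. Used to sharpen the screening model against
#' freezing-point-linked deviations before fitting.
#'
#' @param set a `spectrum_set`.
#' @param lower_pct,upper_pct percentile bounds (default 1 and 99).
#' @return The surviving `spectrum_set`, original order preserved.
#' @export
filter_freezing_point <- function(set, lower_pct = 1, upper_pct = 99) {
  fp <- set$meta$freezing_point
  if (anyNA(fp)) {
    stop("data error: missing freezing_point for sample(s): ",
         paste(utils::head(set$meta$sample_id[is.na(fp)], 5L),
               collapse = ", "))
  }
  qs <- stats::quantile(fp, probs = c(lower_pct, upper_pct) / 100,
                        names = FALSE, type = 1)
  set[fp >= qs[1L] & fp <= qs[2L]]
}

#' Fit the untargeted screening model
#'
#' On preprocessed (band-selected, first-derivative) spectra: standard
#' scaling, 16-component PCA, latent covariance/precision, and the two
#' anomaly score halves (Mahalanobis distance in the latent space and
#' reconstruction residual RMSE in the scaled space). Two trim iterations
#' are run: after each full fit the `ceil(trim_fraction * n)` samples
#' with the highest anomaly scores are removed, then the final model is
#' fitted on the survivors and its score standardisation (mean/SD of the
#' training Mahalanobis distances and residuals) is frozen for all
#' future data.
#'
#' @param set preprocessed `spectrum_set` (see [preprocess_spectra()]).
#' @param n_components number of principal components (default 16).
#' @param trim_fraction fraction trimmed per iteration (default 0.001).
#' @param n_iterations number of fit-and-trim passes before the final
#'   fit (default 2).
#' @return A `screening_model`.
#' @export
fit_screening_model <- function(set, n_components = 16L,
                                trim_fraction = 0.001,
                                n_iterations = 2L) {
  stopifnot(inherits(set, "spectrum_set"))
  current <- set
  trim_history <- integer(0)
  if (trim_fraction > 0 && n_iterations > 0L) {
    for (iter in seq_len(n_iterations)) {
      m <- fit_screen_pass(current, n_components)
      res <- score_with_pass(current, m)
      k <- as.integer(ceiling(trim_fraction * n_samples(current)))
      ord <- order(-res$anomaly_score, res$sample_id)
      drop_idx <- ord[seq_len(k)]
      trim_history <- c(trim_history, k)
      current <- current[-drop_idx]
    }
  }
  m <- fit_screen_pass(current, n_components)
  res <- score_with_pass(current, m)
  m$maha_std <- c(mean = mean(res$mahalanobis),
                  sd = stats::sd(res$mahalanobis))
  m$resid_std <- c(mean = mean(res$residual_rmse),
                   sd = stats::sd(res$residual_rmse))
  if (m$maha_std[["sd"]] <= 0 || m$resid_std[["sd"]] <= 0) {
    stop("fit error: degenerate score standardisation")
  }
  m$trim_history <- trim_history
  m$n_train_final <- n_samples(current)
  class(m) <- "screening_model"
  m
}

# one full fit: scaler -> PCA -> latent covariance/precision
fit_screen_pass <- function(set, n_components) {
  n <- n_samples(set)
  if (n_components >= n) {
    stop("fit error: n_components (", n_components, ") >= n_samples (",
         n, ")")
  }
  scaler <- fit_scaler(set, "standard")
  Xs <- scale_matrix(set$absorbance, scaler)
  pca <- fit_pca(Xs, n_components, center = FALSE)
  latent <- pca_project(Xs, pca)
  latent_mean <- colMeans(latent)
  S <- stats::cov(latent)
  ridge <- 1e-10 * sum(diag(S)) / n_components
  S <- S + diag(ridge, n_components)
  P <- chol2inv(chol(S))
  P <- (P + t(P)) / 2
  list(scaler = scaler, pca = pca, n_components = as.integer(n_components),
       explained_variance = pca$explained_variance,
       ev_ratio = pca$ev_ratio[seq_len(n_components)],
       latent_mean = latent_mean, latent_covariance = S,
       latent_precision = P,
       grid = set$grid, band_id = set$band_id)
}

score_with_pass <- function(set, m) {
  Xs <- scale_matrix(set$absorbance, m$scaler)
  latent <- pca_project(Xs, m$pca)
  d <- mahalanobis_raw(latent, m$latent_mean, m$latent_precision)
  recon <- pca_reconstruct(latent, m$pca)
  r <- sqrt(rowMeans((Xs - recon)^2))
  zd <- (d - mean(d)) / stats::sd(d)
  zr <- (r - mean(r)) / stats::sd(r)
  data.frame(sample_id = set$meta$sample_id, mahalanobis = d,
             residual_rmse = r, anomaly_score = zd + zr,
             stringsAsFactors = FALSE)
}

mahalanobis_raw <- function(latent, mu, precision) {
  diffs <- sweep(latent, 2L, mu)
  sqrt(pmax(rowSums((diffs %*% precision) * diffs), 0))
}

#' Mahalanobis distance in the screening latent space
#'
#' `sqrt((x - mu)' P (x - mu))` with the model's frozen latent mean and
#' (ridge-regularised, symmetrised) precision matrix.
#'
#' @param latent numeric vector of length `n_components`, or a matrix
#'   with one latent vector per row.
#' @param model a fitted `screening_model`.
#' @return Non-negative distance(s).
#' @export
mahalanobis_distance <- function(latent, model) {
  stopifnot(inherits(model, "screening_model"))
  if (is.null(dim(latent))) latent <- matrix(latent, nrow = 1L)
  if (ncol(latent) != model$n_components) {
    stop("shape error: latent has ", ncol(latent), " dims, model expects ",
         model$n_components)
  }
  if (!all(is.finite(latent))) stop("data error: non-finite latent input")
  d <- mahalanobis_raw(latent, model$latent_mean, model$latent_precision)
  if (length(d) == 1L) d[[1L]] else d
}

#' Reconstruction residual (Q residual)
#'
#' RMSE between a scaled spectrum and its reconstruction from the
#' 16-component basis, computed in the model's scaled-derivative space.
#'
#' @param x numeric vector (one already scaled spectrum) or matrix of
#'   scaled spectra in rows. Must be in the model's scaled space, i.e.
#'   after band selection, derivative and [apply_scaler()] with
#'   `model$scaler`.
#' @param model a fitted `screening_model`.
#' @return Residual RMSE per spectrum.
#' @export
reconstruction_residual <- function(x, model) {
  stopifnot(inherits(model, "screening_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$scaler$center)) {
    stop("shape error: spectrum has ", ncol(x), " points, model expects ",
         length(model$scaler$center))
  }
  latent <- pca_project(x, model$pca)
  recon <- pca_reconstruct(latent, model$pca)
  r <- sqrt(rowMeans((x - recon)^2))
  if (length(r) == 1L) r[[1L]] else r
}

#' Spectrum anomaly scores
#'
#' For each spectrum: the Mahalanobis distance and reconstruction
#' residual are standardised with the model's frozen training mean/SD and
#' summed. Scores near zero are average; higher scores are more atypical.
#'
#' @param set preprocessed `spectrum_set` (same preprocessing as the
#'   training data).
#' @param model a fitted `screening_model`.
#' @return data.frame: `sample_id`, `mahalanobis`, `residual_rmse`,
#'   `anomaly_score`, `month` (calendar key `YYYY-MM`), `flagged` (NA
#'   until [flag_monthly()]).
#' @export
anomaly_scores <- function(set, model) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!inherits(model, "screening_model") || is.null(model$maha_std)) {
    stop("state error: model not fitted")
  }
  if (n_points(set) != length(model$scaler$center)) {
    stop("shape error: set has ", n_points(set), " points, model expects ",
         length(model$scaler$center))
  }
  Xs <- scale_matrix(set$absorbance, model$scaler)
  latent <- pca_project(Xs, model$pca)
  d <- mahalanobis_raw(latent, model$latent_mean, model$latent_precision)
  recon <- pca_reconstruct(latent, model$pca)
  r <- sqrt(rowMeans((Xs - recon)^2))
  score <- (d - model$maha_std[["mean"]]) / model$maha_std[["sd"]] +
    (r - model$resid_std[["mean"]]) / model$resid_std[["sd"]]
  data.frame(sample_id = set$meta$sample_id, mahalanobis = d,
             residual_rmse = r, anomaly_score = score,
             month = format(set$meta$timestamp, "%Y-%m"),
             flagged = NA, stringsAsFactors = FALSE)
}

#' Flag atypical spectra at a monthly prevalence
#'
#' Per calendar month, the `floor(prevalence * n_month)` highest-scoring
#' samples are flagged; ties are broken by (score descending, sample_id
#' ascending) so flagging is deterministic.
#'
#' @param results data.frame from [anomaly_scores()].
#' @param prevalence assumed atypical prevalence (default 0.001).
#' @return `results` with the `flagged` column filled in.
#' @export
flag_monthly <- function(results, prevalence = 0.001) {
  stopifnot(all(c("anomaly_score", "month", "sample_id") %in%
                  names(results)))
  results$flagged <- FALSE
  for (m in unique(results$month)) {
    idx <- which(results$month == m)
    k <- max(0L, floor(prevalence * length(idx)))
    if (k > 0L) {
      ord <- idx[order(-results$anomaly_score[idx], results$sample_id[idx])]
      results$flagged[ord[seq_len(k)]] <- TRUE
    }
  }
  results
}

#' @export
print.screening_model <- function(x, ...) {
  cat("<screening_model> ", x$n_components, " components, ",
      length(x$scaler$center), " points; trained on ", x$n_train_final,
      " spectra (trimmed ", paste(x$trim_history, collapse = "+"),
      ")\n  explained variance: ",
      sprintf("%.2f%%", 100 * x$explained_variance), "\n", sep = "")
  invisible(x)
}

#' Instrument separation diagnostic in the screening latent space
#'
#' Mean silhouette of the instrument labels over the latent scores: the
#' screening model must not be more sensitive to one instrument than
#' another, so instruments should NOT form distinct clusters in the
#' latent space. Values below ~0.1 indicate no meaningful instrument
#' clustering; this is a report diagnostic, not a fitting constraint.
#'
#' @param set preprocessed `spectrum_set` (instrument ids in metadata).
#' @param model a fitted `screening_model`.
#' @param max_samples random subsample cap for the pairwise-distance
#'   computation.
#' @param seed subsample seed.
#' @return Mean silhouette width (numeric scalar).
#' @export
instrument_latent_silhouette <- function(set, model, max_samples = 2000L,
                                         seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"),
            inherits(model, "screening_model"))
  idx <- seq_len(n_samples(set))
  if (length(idx) > max_samples) {
    idx <- with_seed(seed, sort(sample(idx, max_samples)))
  }
  sub <- set[idx]
  latent <- pca_project(scale_matrix(sub$absorbance, model$scaler),
                        model$pca)
  silhouette_mean(latent, sub$meta$instrument_id)
}
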