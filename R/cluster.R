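#' Fit the cluster latent space on flagged atypical spectra
#'
#' Robust (median/IQR) scaling followed by PCA; `min(n_components, rank)`
#' components are retained (default 24, targeting ~99.5 percent of the
#' variance on calibrated data).
#'
#' @param set preprocessed `spectrum_set` of flagged atypical spectra.
#' @param n_components maximum number of components (default 24).
#' @return List with `scaler`, `pca`, `n_components`,
#'   `explained_variance`.
#' @export
fit_cluster_latent <- function(set, n_components = 24L) {
  stopifnot(inherits(set, "spectrum_set"))
  if (n_samples(set) < 25L) {
    stop("fit error: need >= 25 atypical spectra, got ", n_samples(set))
  }
  scaler <- fit_scaler(set, "robust")
  Xs <- scale_matrix(set$absorbance, scaler)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > 1e-12 * max(ev))
  if (rank < 2L) stop("fit error: scaled data has rank < 2")
  k <- min(n_components, rank)
  pca <- fit_pca(Xs, k, center = TRUE)
  list(scaler = scaler, pca = pca, n_components = as.integer(k),
       explained_variance = pca$explained_variance,
       grid = set$grid, band_id = set$band_id)
}

#' Project preprocessed spectra into a fitted cluster latent space
#'
#' @param set preprocessed `spectrum_set`.
#' @param latent_fit result of [fit_cluster_latent()] (or a
#'   `cluster_model`).
#' @return Latent matrix, one row per spectrum.
#' @export
cluster_latent <- function(set, latent_fit) {
  if (n_points(set) != length(latent_fit$scaler$center)) {
    stop("shape error: set has ", n_points(set), " points, latent fit has ",
         length(latent_fit$scaler$center))
  }
  pca_project(scale_matrix(as_matrix(set), latent_fit$scaler),
              latent_fit$pca)
}

#' Sweep the number of mixture components
#'
#' Fits one GMM per K in `k_min:k_max` and records basic diagnostics
#' (log-likelihood, BIC, mean silhouette, cluster sizes). Per-K failures
#' are recorded, not fatal.
#'
#' @param latent latent matrix.
#' @param k_min,k_max sweep range (default 4..20).
#' @inheritParams fit_gmm
#' @return List of entries `K`, `gmm` (or NULL), `diagnostics`, `error`.
#' @export
sweep_k <- function(latent, k_min = 4L, k_max = 20L, n_init = 50L,
                    seed = 1L) {
  latent <- as.matrix(latent)
  if (nrow(latent) <= k_max) {
    stop("fit error: need n > k_max (n = ", nrow(latent), ")")
  }
  lapply(seq.int(k_min, k_max), function(K) {
    fit <- tryCatch(fit_gmm(latent, K, n_init = n_init,
                            seed = seed + 1000L * K),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(K = K, gmm = NULL, diagnostics = NULL,
                  error = conditionMessage(fit)))
    }
    n_par <- K - 1 + K * ncol(latent) +
      K * ncol(latent) * (ncol(latent) + 1) / 2
    diag_k <- list(
      loglik = fit$loglik,
      bic = -2 * fit$loglik + n_par * log(nrow(latent)),
      silhouette = silhouette_mean(latent, fit$labels),
      sizes = as.integer(table(factor(fit$labels, levels = seq_len(K))))
    )
    list(K = K, gmm = fit, diagnostics = diag_k, error = NULL)
  })
}

#' Evaluate a cluster solution against the six screening criteria
#'
#' Emits, per cluster: (i) within-cluster mean pairwise latent distance
#' and its ratio to the between-cluster mean distance, (ii) size, (iii)
#' unique-farm proportion, (iv) temporal concentration (max fraction of
#' members in any 14-day window), (v) instrument counts and normalised
#' Shannon entropy, (vi) median and IQR of the six analytes. Missing
#' metadata disables the affected diagnostic only.
#'
#' @param labels integer cluster labels (e.g. `gmm$labels` or final
#'   merged labels).
#' @param set the `spectrum_set` the labels belong to (metadata source).
#' @param latent latent matrix used for the spectral-distance criterion;
#'   optional.
#' @return A `cluster_diagnostics` list of data.frames.
#' @export
evaluate_clusters <- function(labels, set, latent = NULL) {
  stopifnot(length(labels) == n_samples(set))
  labels <- as.integer(labels)
  lev <- sort(unique(labels))
  meta <- set$meta
  sizes <- data.frame(cluster = lev,
                      size = vapply(lev, function(l) sum(labels == l),
                                    integer(1L)))
  within_between <- NULL
  if (!is.null(latent)) {
    D <- as.matrix(stats::dist(as.matrix(latent)))
    within <- vapply(lev, function(l) {
      idx <- which(labels == l)
      if (length(idx) < 2L) return(NA_real_)
      mean(D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    }, numeric(1L))
    between <- vapply(lev, function(l) {
      idx <- which(labels == l)
      other <- which(labels != l)
      if (!length(other)) return(NA_real_)
      mean(D[idx, other, drop = FALSE])
    }, numeric(1L))
    within_between <- data.frame(
      cluster = lev, within = within, between = between,
      ratio = within / between,
      degenerate = !is.finite(within / between))
  }
  farms <- data.frame(
    cluster = lev,
    unique_farm_pct = vapply(lev, function(l) {
      idx <- labels == l
      100 * length(unique(meta$farm_id[idx])) / sum(idx)
    }, numeric(1L)))
  temporal <- data.frame(
    cluster = lev,
    concentration_14d = vapply(lev, function(l) {
      temporal_concentration(meta$timestamp[labels == l], days = 14L)
    }, numeric(1L)))
  inst_tab <- table(factor(labels, levels = lev), meta$instrument_id)
  entropy <- apply(inst_tab, 1L, function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    if (length(p) <= 1L) return(0)
    -sum(p * log(p)) / log(ncol(inst_tab))
  })
  instruments <- data.frame(cluster = lev, entropy = as.numeric(entropy))
  instruments <- cbind(instruments,
                       as.data.frame.matrix(unclass(inst_tab)))
  comp <- do.call(rbind, lapply(analyte_columns(), function(an) {
    if (!an %in% names(meta) || all(is.na(meta[[an]]))) return(NULL)
    do.call(rbind, lapply(lev, function(l) {
      v <- meta[[an]][labels == l]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                            na.rm = TRUE, type = 7)
      data.frame(cluster = l, analyte = an, median = qs[2L],
                 q25 = qs[1L], q75 = qs[3L], iqr = qs[3L] - qs[1L])
    }))
  }))
  structure(list(sizes = sizes, within_between = within_between,
                 farms = farms, temporal = temporal,
                 instruments = instruments, composition = comp),
            class = "cluster_diagnostics")
}

# max fraction of timestamps falling inside any window of `days`
# consecutive calendar days
temporal_concentration <- function(timestamps, days = 2L) {
  if (!length(timestamps)) return(NA_real_)
  d <- as.Date(timestamps, tz = "UTC")
  max(vapply(unique(d), function(d0) {
    mean(d >= d0 & d < d0 + days)
  }, numeric(1L)))
}

#' Merge raw mixture components into final clusters
#'
#' Union-find over the requested pairs; final labels are renumbered
#' 1..m by descending merged training size.
#'
#' @param gmm a fitted `milk_gmm` (its training `labels` supply the
#'   sizes used for renumbering).
#' @param pairs list of length-2 integer vectors of raw component labels
#'   to merge (transitively).
#' @return Integer `merge_map`: `merge_map[raw_label]` is the final
#'   cluster label.
#' @export
merge_clusters <- function(gmm, pairs = list()) {
  K <- gmm$K
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (p in pairs) {
    p <- as.integer(p)
    if (length(p) != 2L || any(p < 1L | p > K)) {
      stop("argument error: merge pair references unknown raw label: ",
           paste(p, collapse = ":"))
    }
    ra <- find(p[1L]); rb <- find(p[2L])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(K), find, integer(1L))
  sizes <- as.integer(table(factor(gmm$labels, levels = seq_len(K))))
  merged_size <- vapply(seq_len(K), function(r) {
    sum(sizes[root == r])
  }, integer(1L))
  roots <- unique(root)
  ord <- roots[order(-merged_size[roots], roots)]
  final_of_root <- integer(K)
  final_of_root[ord] <- seq_along(ord)
  final_of_root[root]
}

#' Assemble a cluster model
#'
#' Convenience wrapper: fit the latent space, fit the GMM at a chosen K,
#' apply merge pairs, and bundle everything needed to project and label
#' new spectra.
#'
#' @inheritParams fit_cluster_latent
#' @inheritParams fit_gmm
#' @param merge_pairs list of raw label pairs for [merge_clusters()].
#' @return A `cluster_model` with `scaler`, `pca`, `gmm`, `merge_map`,
#'   `n_final_clusters`, `labels_final` (training labels after merging),
#'   `best_loglik`.
#' @export
fit_cluster_model <- function(set, K, n_components = 24L, n_init = 50L,
                              seed = 1L, merge_pairs = list()) {
  lf <- fit_cluster_latent(set, n_components)
  latent <- cluster_latent(set, lf)
  gmm <- fit_gmm(latent, K, n_init = n_init, seed = seed)
  merge_map <- merge_clusters(gmm, merge_pairs)
  structure(list(
    scaler = lf$scaler, pca = lf$pca, n_components = lf$n_components,
    explained_variance = lf$explained_variance,
    grid = lf$grid, band_id = lf$band_id,
    gmm = gmm, merge_map = merge_map,
    n_final_clusters = max(merge_map),
    labels_final = merge_map[gmm$labels],
    best_loglik = gmm$loglik
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> K = ", x$gmm$K, " raw components -> ",
      x$n_final_clusters, " final clusters; ", x$n_components,
      " latent dims (", sprintf("%.2f%%", 100 * x$explained_variance),
      " variance)\n", sep = "")
  invisible(x)
}

#' Suggest merges of instrument-split clusters
#'
#' Proposes pairs of clusters whose compositional profiles overlap (each
#' analyte median inside the other cluster's IQR, for all six analytes)
#' while their instrument supports are disjoint and jointly cover all
#' instruments — the signature of one physical cluster split in two by
#' inter-instrument differences. Advisory only.
#'
#' @param diagnostics a `cluster_diagnostics` from [evaluate_clusters()].
#' @return List of length-2 integer vectors (possibly empty).
#' @export
suggest_instrument_merges <- function(diagnostics) {
  inst <- diagnostics$instruments
  comp <- diagnostics$composition
  if (is.null(inst) || is.null(comp)) return(list())
  lev <- inst$cluster
  if (length(lev) < 2L) return(list())
  inst_cols <- setdiff(names(inst), c("cluster", "entropy"))
  support <- lapply(seq_along(lev), function(i) {
    inst_cols[which(as.numeric(inst[i, inst_cols]) > 0)]
  })
  overlaps <- function(a, b) {
    ca <- comp[comp$cluster == a, ]
    cb <- comp[comp$cluster == b, ]
    an <- intersect(ca$analyte, cb$analyte)
    if (!length(an)) return(FALSE)
    all(vapply(an, function(x) {
      ra <- ca[ca$analyte == x, ]
      rb <- cb[cb$analyte == x, ]
      ra$median >= rb$q25 && ra$median <= rb$q75 &&
        rb$median >= ra$q25 && rb$median <= ra$q75
    }, logical(1L)))
  }
  out <- list()
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i) next
      disjoint <- !length(intersect(support[[i]], support[[j]]))
      complete <- setequal(union(support[[i]], support[[j]]), inst_cols)
      if (disjoint && complete && overlaps(lev[i], lev[j])) {
        out[[length(out) + 1L]] <- c(lev[i], lev[j])
      }
    }
  }
  out
}
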