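#' Default classifier hyperparameter grid
#'
#' RBF support-vector classifier: regularisation `cost` in
#' {0.1, 1, 10, 100} crossed with kernel width `gamma` at {0.1, 1, 10}
#' times the scale heuristic `1 / (n_dims * Var(X))`.
#'
#' @return List with `cost` and `gamma_mult`.
#' @export
default_svm_grid <- function() {
  list(cost = c(0.1, 1, 10, 100), gamma_mult = c(0.1, 1, 10))
}

#' Weighted F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall; 0 when
#' undefined), averaged with weights proportional to true-class support.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return Score in [0, 1].
#' @export
weighted_f1 <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("argument error: label vectors differ in length")
  }
  if (!length(true_labels)) stop("argument error: empty labels")
  classes <- unique(true_labels)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1L))
  support <- vapply(classes, function(cl) sum(true_labels == cl),
                    numeric(1L))
  sum(f1 * support) / sum(support)
}

# seeded stratified fold assignment: per class, shuffled round-robin
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    fold
  })
}

#' Fit the cluster-assignment classifier
#'
#' RBF support-vector classifier (one-vs-one) on the cluster latent
#' space with the final cluster labels as classes. The grid is searched
#' by mean weighted F1 over seeded stratified cross-validation folds;
#' the best point is refitted on all data. Classes smaller than
#' `cv_folds` trigger a warning and a fold-count reduction to the
#' smallest class size.
#'
#' @param latent training latent matrix.
#' @param labels final cluster labels (integer).
#' @param grid see [default_svm_grid()].
#' @param cv_folds number of stratified folds (default 5).
#' @param seed integer seed (fold assignment).
#' @param transforms optional `cluster_model` whose frozen scaler/basis
#'   project new raw (preprocessed) spectra into this latent space.
#' @param gate_gmm optional `milk_gmm` used as a typicality gate: new
#'   samples whose mixture log-density falls below the
#'   `gate_percentile` percentile of the training densities are marked
#'   unassignable (the primary label is untouched).
#' @param gate_percentile percentile (0..100) for the density gate.
#' @return A `classifier_model`.
#' @export
fit_classifier <- function(latent, labels, grid = default_svm_grid(),
                           cv_folds = 5L, seed = 1L, transforms = NULL,
                           gate_gmm = NULL, gate_percentile = 1) {
  X <- as.matrix(latent)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("fit error: single class")
  min_class <- min(table(labels))
  k <- cv_folds
  if (min_class < cv_folds) {
    k <- max(2L, as.integer(min_class))
    warning("smallest class has ", min_class, " members; reducing folds to ",
            k)
  }
  g0 <- gamma_scale(X)
  fold <- stratified_folds(labels, k, seed)
  combos <- expand.grid(cost = grid$cost, gamma_mult = grid$gamma_mult,
                        KEEP.OUT.ATTRS = FALSE)
  cv_scores <- vapply(seq_len(nrow(combos)), function(i) {
    C <- combos$cost[i]
    gamma <- combos$gamma_mult[i] * g0
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- svm_ovo_fit(X[tr, , drop = FALSE], labels[tr], C, gamma)
      pred <- svm_ovo_predict(fit, X[!tr, , drop = FALSE])
      weighted_f1(labels[!tr], pred)
    }, numeric(1L)))
  }, numeric(1L))
  best <- which.max(cv_scores)  # first maximum: smaller cost, then gamma
  C <- combos$cost[best]
  gamma <- combos$gamma_mult[best] * g0
  svm <- svm_ovo_fit(X, labels, C, gamma)
  gate <- NULL
  if (!is.null(gate_gmm)) {
    dens <- gmm_log_density(gate_gmm, X)
    gate <- list(gmm = gate_gmm,
                 threshold = stats::quantile(dens, gate_percentile / 100,
                                             names = FALSE, type = 7),
                 percentile = gate_percentile)
  }
  structure(list(
    svm = svm, classes = classes,
    cv_f1_weighted = cv_scores[best],
    grid = grid, cv_scores = cbind(combos, f1 = cv_scores),
    best_params = list(cost = C, gamma = gamma, gamma_scale = g0),
    cv_folds_used = k,
    transforms = transforms, gate = gate
  ), class = "classifier_model")
}

#' Assign spectra to clusters
#'
#' Applies the frozen robust scaler and PCA basis (when `new_set` is a
#' preprocessed `spectrum_set` and the classifier carries transforms),
#' then the support-vector decision model. Every sample receives exactly
#' one label from the training classes; when a density gate is present,
#' an `unassignable` column marks samples whose GMM log-density falls
#' below the gate threshold.
#'
#' @param new_set preprocessed `spectrum_set` or latent matrix.
#' @param classifier a `classifier_model`.
#' @return data.frame: `sample_id` (if available), `label`,
#'   `gmm_log_density` and `unassignable` (if gated).
#' @export
classify_spectra <- function(new_set, classifier) {
  stopifnot(inherits(classifier, "classifier_model"))
  sample_id <- NULL
  if (inherits(new_set, "spectrum_set")) {
    if (is.null(classifier$transforms)) {
      stop("shape error: classifier has no transforms; pass a latent matrix")
    }
    latent <- cluster_latent(new_set, classifier$transforms)
    sample_id <- new_set$meta$sample_id
  } else {
    latent <- as.matrix(new_set)
  }
  if (ncol(latent) != ncol(classifier$svm$X)) {
    stop("shape error: latent has ", ncol(latent), " dims, classifier has ",
         ncol(classifier$svm$X))
  }
  label <- svm_ovo_predict(classifier$svm, latent)
  out <- data.frame(label = label)
  if (!is.null(sample_id)) out <- cbind(data.frame(sample_id = sample_id,
                                                   stringsAsFactors = FALSE),
                                        out)
  if (!is.null(classifier$gate)) {
    dens <- gmm_log_density(classifier$gate$gmm, latent)
    out$gmm_log_density <- dens
    out$unassignable <- dens < classifier$gate$threshold
  }
  out
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("<classifier_model> RBF SVC, ", length(x$classes), " classes; CV ",
      "weighted F1 = ", sprintf("%.4f", x$cv_f1_weighted),
      " (cost = ", x$best_params$cost, ", gamma = ",
      signif(x$best_params$gamma, 3), ")\n", sep = "")
  invisible(x)
}
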