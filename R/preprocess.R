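#' Default wavenumber band selection
#'
#' The three mid-IR windows retained for screening: 925-1600, 1690-1900
#' and 2700-2971 cm^-1 (closed intervals). They bracket the lactose,
#' urea/protein, fat carbonyl and fat C-H regions while excluding the
#' water-saturated parts of the spectrum.
#'
#' @return A `band_selection`: list of `c(low, high)` intervals.
#' @export
default_bands <- function() {
  band_selection(list(c(925, 1600), c(1690, 1900), c(2700, 2971)))
}

#' @rdname default_bands
#' @param bands list of numeric `c(low, high)` pairs, non-overlapping.
#' @export
band_selection <- function(bands) {
  bands <- lapply(bands, as.numeric)
  for (b in bands) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("each band must be c(low, high) with low < high")
    }
  }
  ord <- order(vapply(bands, `[`, numeric(1L), 1L))
  bands <- bands[ord]
  if (length(bands) > 1L) {
    for (i in seq_len(length(bands) - 1L)) {
      if (bands[[i]][2] >= bands[[i + 1L]][1]) stop("bands must not overlap")
    }
  }
  structure(bands, class = "band_selection")
}

#' Restrict a spectrum set to selected wavenumber bands
#'
#' Keeps exactly the grid points whose wavenumber lies inside any of the
#' closed intervals, preserving point order, and records per-point band
#' membership so the derivative can be taken within bands only.
#'
#' @param set a `spectrum_set`.
#' @param selection a `band_selection`; defaults to [default_bands()].
#' @return A `spectrum_set` on the reduced grid.
#' @export
select_bands <- function(set, selection = default_bands()) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!inherits(selection, "band_selection")) {
    selection <- band_selection(selection)
  }
  band_of <- rep(NA_integer_, length(set$grid))
  for (i in seq_along(selection)) {
    b <- selection[[i]]
    band_of[set$grid >= b[1] & set$grid <= b[2]] <- i
  }
  keep <- which(!is.na(band_of))
  if (!length(keep)) stop("selection error: no grid point falls in any band")
  spectrum_set(set$absorbance[, keep, drop = FALSE], set$meta,
               set$grid[keep], band_id = band_of[keep])
}

# contiguous segments of the (possibly band-selected) grid; falls back to
# gap detection on the spacing when no band_id is recorded
grid_segments <- function(set) {
  p <- n_points(set)
  if (!is.null(set$band_id)) {
    ids <- set$band_id
  } else if (p >= 2L) {
    gap <- abs(diff(set$grid))
    step <- stats::median(gap)
    ids <- cumsum(c(1L, as.integer(gap > 1.5 * step)))
  } else {
    ids <- rep(1L, p)
  }
  split(seq_len(p), ids)
}

#' First-derivative spectra
#'
#' First derivative in grid-index units, taken independently within
#' each contiguous band (no differencing across band gaps). The tested
#' default is the plain finite difference: central differences on
#' interior points, one-sided at band edges. A Savitzky-Golay
#' derivative (local polynomial fit, default window 7 / order 2,
#' shifted windows at band edges) is available as a config option. The
#' point count is unchanged either way.
#'
#' @param set a `spectrum_set`, typically after [select_bands()].
#' @param method `"finite_difference"` (default) or `"savitzky_golay"`.
#' @param window,order Savitzky-Golay window length (odd) and
#'   polynomial order.
#' @return A `spectrum_set` of derivative spectra.
#' @export
first_derivative <- function(set,
                             method = c("finite_difference",
                                        "savitzky_golay"),
                             window = 7L, order = 2L) {
  stopifnot(inherits(set, "spectrum_set"))
  method <- match.arg(method)
  segs <- grid_segments(set)
  X <- set$absorbance
  D <- X
  min_pts <- if (method == "finite_difference") 3L else as.integer(window)
  for (seg in segs) {
    m <- length(seg)
    if (m < min_pts) {
      stop("preprocessing error: band with fewer than ", min_pts,
           " points (", m, ")")
    }
    xs <- X[, seg, drop = FALSE]
    if (method == "finite_difference") {
      D[, seg[1L]] <- xs[, 2L] - xs[, 1L]
      D[, seg[m]] <- xs[, m] - xs[, m - 1L]
      interior <- 2:(m - 1L)
      D[, seg[interior]] <- (xs[, interior + 1L, drop = FALSE] -
                               xs[, interior - 1L, drop = FALSE]) / 2
    } else {
      D[, seg] <- xs %*% sg_derivative_operator(m, window, order)
    }
  }
  spectrum_set(D, set$meta, set$grid, band_id = set$band_id)
}

# m x m linear operator whose columns hold, per output point, the
# Savitzky-Golay first-derivative weights of its (edge-shifted) window
sg_derivative_operator <- function(m, window = 7L, order = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (order >= window) stop("Savitzky-Golay order must be < window")
  half <- window %/% 2L
  op <- matrix(0, m, m)
  for (i in seq_len(m)) {
    lo <- min(max(1L, i - half), m - window + 1L)
    idx <- lo:(lo + window - 1L)
    A <- outer(idx - i, 0:order, `^`)  # offsets relative to target point
    # derivative at offset 0 = coefficient of the linear term
    w <- solve(crossprod(A), t(A))[2L, ]
    op[idx, i] <- w
  }
  op
}

#' Band selection + first derivative in one call
#'
#' The canonical preprocessing applied before every modelling stage.
#'
#' @inheritParams select_bands
#' @inheritParams first_derivative
#' @param derivative take the first derivative after band selection.
#' @return A preprocessed `spectrum_set`.
#' @export
preprocess_spectra <- function(set, selection = default_bands(),
                               derivative = TRUE,
                               method = "finite_difference",
                               window = 7L, order = 2L) {
  out <- select_bands(set, selection)
  if (derivative) out <- first_derivative(out, method, window, order)
  out
}

#' Fit a per-point scaler
#'
#' `standard` centres each retained point to zero mean / unit variance;
#' `robust` uses the median and interquartile range (quartiles by linear
#' interpolation, R quantile type 7). Points with zero dispersion get
#' scale 1 (their transformed values are exactly 0) with a warning.
#'
#' @param x a `spectrum_set` or numeric matrix (samples in rows).
#' @param kind `"standard"` or `"robust"`.
#' @return A `scaler_params` object with `kind`, `center` and `scale`.
#' @export
fit_scaler <- function(x, kind = c("standard", "robust")) {
  kind <- match.arg(kind)
  X <- as_matrix(x)
  if (nrow(X) < 2L) stop("fit error: scaler needs at least 2 samples")
  if (kind == "standard") {
    center <- colMeans(X)
    scale <- sqrt(colSums(sweep(X, 2L, center)^2) / (nrow(X) - 1L))
  } else {
    center <- apply(X, 2L, stats::median)
    qs <- apply(X, 2L, stats::quantile, probs = c(0.25, 0.75),
                names = FALSE, type = 7)
    scale <- qs[2L, ] - qs[1L, ]
  }
  degenerate <- !is.finite(scale) | scale <= 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " point(s) with zero dispersion; scale set to 1")
    scale[degenerate] <- 1
  }
  structure(list(kind = kind, center = unname(center),
                 scale = unname(scale),
                 degenerate = unname(which(degenerate))),
            class = "scaler_params")
}

#' Apply (or invert) a fitted scaler
#'
#' Computes `(x - center) / scale` pointwise with the frozen training
#' parameters; `invert_scaler` undoes it exactly.
#'
#' @param x a `spectrum_set` or numeric matrix.
#' @param params a `scaler_params` from [fit_scaler()].
#' @return Same type as `x`, transformed.
#' @export
apply_scaler <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  X <- as_matrix(x)
  if (ncol(X) != length(params$center)) {
    stop("shape error: data has ", ncol(X), " points, scaler has ",
         length(params$center))
  }
  Xs <- sweep(sweep(X, 2L, params$center), 2L, params$scale, "/")
  rewrap(x, Xs)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  X <- as_matrix(x)
  if (ncol(X) != length(params$center)) {
    stop("shape error: data has ", ncol(X), " points, scaler has ",
         length(params$center))
  }
  rewrap(x, sweep(sweep(X, 2L, params$scale, "*"), 2L, params$center, "+"))
}

#' Extract the absorbance matrix from a spectrum set (or pass through)
#' @param x a `spectrum_set` or matrix.
#' @return Numeric matrix, samples in rows.
#' @export
as_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) x$absorbance else as.matrix(x)
}

# matrix-only scaling used on hot paths (no spectrum_set revalidation)
scale_matrix <- function(X, params) {
  sweep(sweep(X, 2L, params$center), 2L, params$scale, "/")
}

rewrap <- function(template, X) {
  if (inherits(template, "spectrum_set")) {
    spectrum_set(X, template$meta, template$grid, band_id = template$band_id)
  } else {
    X
  }
}

#' Principal component analysis of scaled spectra
#'
#' Eigendecomposition of the p x p covariance of already-scaled data.
#' Eigenvector signs are fixed (largest-magnitude loading positive) so
#' results do not depend on the LAPACK build. `pca_project` /
#' `pca_reconstruct` map between the data space and the latent space.
#'
#' @param X numeric matrix, samples in rows (already scaled).
#' @param n_components number of components to retain (< `nrow(X)`).
#' @param center centre columns by their mean before decomposition
#'   (disable for standard-scaled data, which is centred already).
#' @return List: `center`, `rotation` (p x k), `eigenvalues` (all p),
#'   `ev_ratio` (per-component explained-variance ratios),
#'   `explained_variance` (cumulative over the retained components).
#' @export
fit_pca <- function(X, n_components, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_components >= n) {
    stop("fit error: n_components (", n_components,
         ") must be < n_samples (", n, ")")
  }
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, ctr)
  C <- crossprod(Xc) / (n - 1L)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  k <- min(n_components, ncol(X))
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(center = ctr, rotation = V, eigenvalues = lambda,
       ev_ratio = lambda / sum(lambda),
       explained_variance = sum(lambda[seq_len(k)]) / sum(lambda))
}

#' @rdname fit_pca
#' @param latent latent-space matrix (samples in rows).
#' @param pca a fitted PCA from `fit_pca`.
#' @export
pca_project <- function(X, pca) {
  sweep(as.matrix(X), 2L, pca$center) %*% pca$rotation
}

#' @rdname fit_pca
#' @export
pca_reconstruct <- function(latent, pca) {
  sweep(latent %*% t(pca$rotation), 2L, pca$center, "+")
}
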