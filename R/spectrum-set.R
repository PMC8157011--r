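#' Reserved metadata column names
#'
#' Column names that every spectra table must carry next to the spectral
#' columns: identifiers, acquisition timestamp, and the six FT-IR-predicted
#' milk analytes.
#'
#' @return Character vector of the ten reserved column names.
#' @export
meta_columns <- function() {
  c("sample_id", "farm_id", "instrument_id", "timestamp",
    "fat", "protein", "lactose", "urea", "freezing_point",
    "milk_fat_acidity")
}

analyte_columns <- function() {
  c("fat", "protein", "lactose", "urea", "freezing_point",
    "milk_fat_acidity")
}

#' Default mid-IR wavenumber grid
#'
#' The acquisition grid used throughout: 1060 points, uniformly spaced,
#' descending from 5012 to 926 cm^-1.
#'
#' @param n_points number of grid points.
#' @param from,to first and last wavenumber in cm^-1.
#' @return Numeric vector of wavenumbers, strictly descending.
#' @export
default_wavenumber_grid <- function(n_points = 1060L, from = 5012, to = 926) {
  seq(from, to, length.out = n_points)
}

#' Construct a spectrum set
#'
#' Bundles an absorbance matrix (one row per sample) with its wavenumber
#' grid and aligned per-sample metadata. Grids supplied in ascending order
#' are normalised to the internal descending convention, reordering the
#' matrix columns accordingly.
#'
#' @param absorbance numeric matrix, `n_samples x n_points`.
#' @param meta data.frame with the columns of [meta_columns()], one row per
#'   spectrum. `timestamp` may be character (ISO-8601) or POSIXct.
#' @param grid numeric wavenumber vector (cm^-1), strictly monotonic,
#'   length `ncol(absorbance)`.
#' @param band_id optional integer vector marking, per grid point, which
#'   contiguous band it belongs to (set by [select_bands()]).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, meta, grid, band_id = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (!is.numeric(grid)) stop("`grid` must be numeric wavenumbers")
  grid <- as.numeric(grid)
  if (ncol(absorbance) != length(grid)) {
    stop("ncol(absorbance) [", ncol(absorbance), "] != length(grid) [",
         length(grid), "]")
  }
  d <- diff(grid)
  if (length(grid) > 1L && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotonic")
  }
  if (length(grid) > 1L && all(d > 0)) {
    # normalise ascending input to the internal descending convention
    idx <- rev(seq_along(grid))
    grid <- grid[idx]
    absorbance <- absorbance[, idx, drop = FALSE]
    if (!is.null(band_id)) band_id <- band_id[idx]
    message("ascending wavenumber grid reordered to descending")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(meta_columns(), names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing reserved column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(meta) != nrow(absorbance)) {
    stop("metadata rows [", nrow(meta), "] != spectra rows [",
         nrow(absorbance), "]")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$farm_id <- as.character(meta$farm_id)
  meta$instrument_id <- as.character(meta$instrument_id)
  meta$timestamp <- parse_timestamp(meta$timestamp)
  for (col in analyte_columns()) meta[[col]] <- as.numeric(meta[[col]])
  if (nrow(absorbance) > 0L && !all(is.finite(absorbance))) {
    stop("absorbance matrix contains non-finite values")
  }
  dimnames(absorbance) <- NULL
  rownames(meta) <- NULL
  structure(
    list(grid = grid, absorbance = absorbance, meta = meta,
         band_id = band_id),
    class = "spectrum_set"
  )
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x))) {
    stop("timestamp not parseable as ISO-8601: ",
         paste(utils::head(x[is.na(out) & !is.na(x)], 3L), collapse = ", "))
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", n_samples(x), " spectra x ", n_points(x),
      " points [", format(max(x$grid)), " .. ", format(min(x$grid)),
      " cm^-1]\n", sep = "")
  if (n_samples(x) > 0L) {
    rng <- range(x$meta$timestamp)
    cat("  acquired ", format(rng[1], "%Y-%m-%d"), " .. ",
        format(rng[2], "%Y-%m-%d"), "; ",
        length(unique(x$meta$farm_id)), " farms, ",
        length(unique(x$meta$instrument_id)), " instruments\n", sep = "")
  }
  invisible(x)
}

#' Number of spectra / grid points in a spectrum set
#' @param x a `spectrum_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_points <- function(x) ncol(x$absorbance)

#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$absorbance[i, , drop = FALSE], x$meta[i, , drop = FALSE],
               x$grid, band_id = x$band_id)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Random train/test split indices
#'
#' Seeded uniform split; the training set gets `floor(train_frac * n)`
#' samples (e.g. 5671 flagged spectra at 75:25 give 4253 for training).
#'
#' @param n number of samples.
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, train_frac = 0.75, seed = 1L) {
  stopifnot(n >= 2L, train_frac > 0, train_frac < 1)
  with_seed(seed, {
    n_train <- floor(train_frac * n)
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}
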