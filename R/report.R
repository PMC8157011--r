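#' Cluster size table
#'
#' @param labels cluster labels.
#' @return data.frame `cluster`, `size`, `pct` (percent of all labelled
#'   spectra, rounded to 2 decimals).
#' @export
cluster_sizes <- function(labels) {
  stopifnot(length(labels) >= 1L)
  tab <- table(labels)
  data.frame(cluster = names(tab), size = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(labels), 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unique-farm proportion per cluster
#'
#' `100 * distinct farms / cluster size`: low values mean a cluster is
#' dominated by few farms.
#'
#' @param labels cluster labels.
#' @param farm_ids farm identifiers aligned with `labels`.
#' @return data.frame `cluster`, `size`, `n_farms`, `unique_farm_pct`.
#' @export
unique_farm_proportion <- function(labels, farm_ids) {
  stopifnot(length(labels) == length(farm_ids))
  lev <- sort(unique(labels))
  out <- do.call(rbind, lapply(lev, function(l) {
    idx <- labels == l
    data.frame(cluster = l, size = sum(idx),
               n_farms = length(unique(farm_ids[idx])))
  }))
  out$unique_farm_pct <- 100 * out$n_farms / out$size
  out
}

#' Mean number of spectra per farm, per cluster
#'
#' @inheritParams unique_farm_proportion
#' @return data.frame `cluster`, `spectra_per_farm` (cluster size over
#'   distinct farms; display-rounded value in `spectra_per_farm_1d`).
#' @export
spectra_per_farm <- function(labels, farm_ids) {
  out <- unique_farm_proportion(labels, farm_ids)
  out$spectra_per_farm <- out$size / out$n_farms
  out$spectra_per_farm_1d <- round(out$spectra_per_farm, 1L)
  out[c("cluster", "size", "n_farms", "spectra_per_farm",
        "spectra_per_farm_1d")]
}

#' Temporal profile per cluster
#'
#' ISO-8601 week binning; each cluster's weekly counts are normalised by
#' that cluster's maximum weekly count (rows in [0, 1]). Also reports,
#' per cluster, the maximum fraction of members in any window of
#' `concentration_days` consecutive days.
#'
#' @param labels cluster labels.
#' @param timestamps POSIXct acquisition times aligned with `labels`.
#' @param concentration_days window width for the concentration
#'   statistic (default 2, flagging single instrument events).
#' @return List with `profile` (cluster x ISO-week matrix) and
#'   `concentration` (data.frame `cluster`, `concentration`).
#' @export
temporal_profile <- function(labels, timestamps, concentration_days = 2L) {
  stopifnot(length(labels) == length(timestamps))
  week <- format(as.Date(timestamps, tz = "UTC"), "%G-W%V")
  lev <- sort(unique(labels))
  weeks <- sort(unique(week))
  counts <- table(factor(labels, levels = lev),
                  factor(week, levels = weeks))
  profile <- t(apply(counts, 1L, function(r) {
    if (max(r) > 0) r / max(r) else r
  }))
  dimnames(profile) <- list(as.character(lev), weeks)
  concentration <- data.frame(
    cluster = lev,
    concentration = vapply(lev, function(l) {
      temporal_concentration(timestamps[labels == l],
                             days = concentration_days)
    }, numeric(1L)))
  list(profile = profile, concentration = concentration)
}

#' Compositional profile per cluster with a reference band
#'
#' Per cluster and analyte: min, quartiles and max (for the training set
#' and, when given, the test set). The reference band is the mean plus
#' or minus `1.96 * SD / sqrt(n)` of the screening reference population
#' (normal-approximation 95 percent confidence interval).
#'
#' @param labels cluster labels for `meta`.
#' @param meta metadata data.frame of the clustered (training) spectra.
#' @param reference_meta metadata of the screening training population.
#' @param test_labels,test_meta optional test-set labels/metadata.
#' @return List with `profile` (long data.frame) and `reference`
#'   (analyte, mean, ci_low, ci_high).
#' @export
composition_profile <- function(labels, meta, reference_meta,
                                test_labels = NULL, test_meta = NULL) {
  summarise <- function(lbls, md, split) {
    do.call(rbind, lapply(analyte_columns(), function(an) {
      if (!an %in% names(md) || all(is.na(md[[an]]))) {
        warning("analyte ", an, " missing; skipped")
        return(NULL)
      }
      do.call(rbind, lapply(sort(unique(lbls)), function(l) {
        v <- md[[an]][lbls == l]
        qs <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                              na.rm = TRUE, type = 7)
        data.frame(split = split, cluster = l, analyte = an,
                   min = qs[1L], q25 = qs[2L], median = qs[3L],
                   q75 = qs[4L], max = qs[5L], stringsAsFactors = FALSE)
      }))
    }))
  }
  profile <- summarise(labels, meta, "train")
  if (!is.null(test_labels)) {
    profile <- rbind(profile, summarise(test_labels, test_meta, "test"))
  }
  reference <- do.call(rbind, lapply(analyte_columns(), function(an) {
    v <- reference_meta[[an]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(analyte = an, mean = mean(v),
               ci_low = mean(v) - 1.96 * se, ci_high = mean(v) + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  list(profile = profile, reference = reference)
}

#' Mean spectral deviation per cluster
#'
#' Per cluster: the mean preprocessed spectrum minus the typical
#' population's mean preprocessed spectrum, per retained grid point.
#'
#' @param labels cluster labels.
#' @param preprocessed_set `spectrum_set` of the clustered spectra, with
#'   the same preprocessing as `typical_mean`.
#' @param typical_mean numeric vector: mean preprocessed spectrum of the
#'   screening training population.
#' @return Matrix, one row per cluster (rownames = cluster labels),
#'   columns = retained wavenumbers.
#' @export
mean_spectral_deviation <- function(labels, preprocessed_set, typical_mean) {
  stopifnot(length(labels) == n_samples(preprocessed_set))
  if (length(typical_mean) != n_points(preprocessed_set)) {
    stop("shape error: typical_mean has ", length(typical_mean),
         " points, set has ", n_points(preprocessed_set))
  }
  lev <- sort(unique(labels))
  out <- t(vapply(lev, function(l) {
    colMeans(preprocessed_set$absorbance[labels == l, , drop = FALSE]) -
      typical_mean
  }, numeric(n_points(preprocessed_set))))
  dimnames(out) <- list(as.character(lev),
                        formatC(preprocessed_set$grid, digits = 6,
                                format = "g"))
  out
}

#' Full cluster characterisation report
#'
#' Bundles every diagnostic table: sizes, farm proportions, temporal
#' profile, composition vs reference band, and mean spectral deviation.
#'
#' @param labels final cluster labels of the clustered spectra.
#' @param set the clustered (preprocessed) `spectrum_set`.
#' @param reference_meta metadata of the screening training population.
#' @param typical_mean mean preprocessed typical spectrum.
#' @param test_labels,test_meta optional test-set assignment.
#' @return A `cluster_report` list.
#' @export
cluster_report <- function(labels, set, reference_meta, typical_mean,
                           test_labels = NULL, test_meta = NULL) {
  structure(list(
    sizes = cluster_sizes(labels),
    farms = spectra_per_farm(labels, set$meta$farm_id),
    temporal = temporal_profile(labels, set$meta$timestamp),
    composition = composition_profile(labels, set$meta, reference_meta,
                                      test_labels, test_meta),
    deviation = mean_spectral_deviation(labels, set, typical_mean)
  ), class = "cluster_report")
}

#' Write a cluster report as CSV tables
#'
#' @param report a `cluster_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$sizes, file.path(dir, "sizes.csv"))
  data.table::fwrite(report$farms, file.path(dir, "farms.csv"))
  prof <- as.data.frame(report$temporal$profile)
  prof <- cbind(cluster = rownames(report$temporal$profile), prof)
  data.table::fwrite(prof, file.path(dir, "temporal.csv"))
  data.table::fwrite(report$temporal$concentration,
                     file.path(dir, "temporal_concentration.csv"))
  data.table::fwrite(report$composition$profile,
                     file.path(dir, "composition.csv"))
  data.table::fwrite(report$composition$reference,
                     file.path(dir, "composition_reference.csv"))
  dev <- as.data.frame(report$deviation)
  dev <- cbind(cluster = rownames(report$deviation), dev)
  data.table::fwrite(dev, file.path(dir, "deviation.csv"))
  invisible(dir)
}
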