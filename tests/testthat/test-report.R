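test_that("cluster size percentages match the printed-count arithmetic", {
  labels <- rep(c(9L, 4L, 1L), times = c(11L, 1554L, 4253L - 11L - 1554L))
  sz <- cluster_sizes(labels)
  expect_equal(sz$pct[sz$cluster == "9"], 0.26)
  expect_equal(sz$pct[sz$cluster == "4"], 36.54)
  expect_equal(sum(sz$size), 4253L)
  expect_equal(sum(sz$pct), 100, tolerance = 0.01)
  expect_equal(cluster_sizes(rep(1L, 7L))$pct, 100)
})

test_that("farm proportion and spectra-per-farm match the printed cluster", {
  farms <- c(sprintf("F%03d", 1:227),
             rep(sprintf("F%03d", 1:151), 2L))  # 529 spectra, 227 farms
  labels <- rep(7L, 529L)
  fp <- unique_farm_proportion(labels, farms)
  expect_equal(fp$n_farms, 227L)
  expect_equal(round(fp$unique_farm_pct, 1L), 42.9)
  spf <- spectra_per_farm(labels, farms)
  expect_equal(spf$spectra_per_farm_1d, 2.3)

  one_farm <- unique_farm_proportion(rep(1L, 10L), rep("F1", 10L))
  expect_equal(one_farm$unique_farm_pct, 10)
  all_diff <- unique_farm_proportion(rep(1L, 8L), sprintf("F%d", 1:8))
  expect_equal(all_diff$unique_farm_pct, 100)
  expect_equal(spectra_per_farm(rep(1L, 8L),
                                sprintf("F%d", 1:8))$spectra_per_farm, 1)
})

test_that("temporal profiles are max-normalised per cluster", {
  ts <- as.POSIXct("2018-01-03", tz = "UTC") + (0:363) * 86400
  labels <- rep(1L, 364L)
  tp <- temporal_profile(labels, ts)
  expect_true(all(tp$profile >= 0 & tp$profile <= 1))
  expect_true(all(apply(tp$profile, 1L, max) == 1))
  expect_true(all(tp$profile[1L, ] > 0))  # uniform coverage: no empty week

  single <- temporal_profile(c(1L, 2L, 2L),
                             as.POSIXct(c("2018-01-01", "2018-05-01",
                                          "2018-05-02"), tz = "UTC"))
  expect_equal(sum(single$profile["1", ] == 1), 1L)
  expect_equal(sum(single$profile["1", ] > 0), 1L)
  expect_equal(single$concentration$concentration, c(1, 1))
})

test_that("the planted fringe cluster is concentrated on two days", {
  fx <- study_small()
  fringe_cl <- as.integer(names(which.max(
    table(fx$gmm$labels[fx$truth == "INSTRUMENT_FRINGE"]))))
  tp <- temporal_profile(fx$gmm$labels, fx$atyp$meta$timestamp)
  conc <- tp$concentration$concentration[
    tp$concentration$cluster == fringe_cl]
  expect_gte(conc, 0.99)
})

test_that("composition profiles sit where the archetypes put them", {
  fx <- study_small()
  ref_meta <- fx$study$set$meta
  cp <- composition_profile(fx$gmm$labels, fx$atyp$meta, ref_meta)
  ref <- cp$reference
  water_cl <- as.integer(names(which.max(
    table(fx$gmm$labels[fx$truth == "EXTRANEOUS_WATER"]))))
  pc_cl <- as.integer(names(which.max(
    table(fx$gmm$labels[fx$truth == "PROTEIN_CARB_ADULTERATION"]))))
  med <- function(cl, an) {
    cp$profile$median[cp$profile$cluster == cl &
                        cp$profile$analyte == an &
                        cp$profile$split == "train"]
  }
  band <- function(an) ref[ref$analyte == an, ]
  expect_lt(med(water_cl, "protein"), band("protein")$ci_low)
  expect_lt(med(water_cl, "lactose"), band("lactose")$ci_low)
  expect_gt(med(water_cl, "freezing_point"), band("freezing_point")$ci_high)
  expect_gt(med(pc_cl, "protein"), band("protein")$ci_high)
  expect_lt(med(pc_cl, "freezing_point"), band("freezing_point")$ci_low)

  # a reference population profiled against itself sits inside its band
  self <- composition_profile(rep(1L, nrow(ref_meta)), ref_meta, ref_meta)
  for (an in c("fat", "protein", "lactose")) {
    m <- self$profile$median[self$profile$analyte == an]
    expect_gt(m, band(an)$ci_low - 0.05)
    expect_lt(m, band(an)$ci_high + 0.05)
  }
})

test_that("mean spectral deviation localises the fat bands", {
  fx <- study_small()
  typical_ids <- fx$study$truth$sample_id[
    fx$study$truth$truth_label == "typical"]
  typ_pp <- fx$pp[fx$pp$meta$sample_id %in% typical_ids[1:2000]]
  typ_mean <- colMeans(typ_pp$absorbance)
  dev <- mean_spectral_deviation(fx$gmm$labels, fx$atyp, typ_mean)
  fat_cl <- as.character(names(which.max(
    table(fx$gmm$labels[fx$truth == "HIGH_FAT"]))))

  # localisation is asserted in absorbance terms (band selection only):
  # the high-fat cluster absorbs more around 1750 and 2860 cm^-1
  raw_sel <- select_bands(fx$study$set)
  raw_atyp <- raw_sel[raw_sel$meta$sample_id %in% fx$atyp$meta$sample_id]
  raw_typ <- raw_sel[raw_sel$meta$sample_id %in% typical_ids[1:2000]]
  lab_raw <- fx$gmm$labels[match(raw_atyp$meta$sample_id,
                                 fx$atyp$meta$sample_id)]
  dev_ab <- mean_spectral_deviation(lab_raw, raw_atyp,
                                    colMeans(raw_typ$absorbance))
  grid <- raw_atyp$grid
  fat_windows <- (grid >= 1730 & grid <= 1770) |
    (grid >= 2840 & grid <= 2880)
  row <- dev_ab[fat_cl, ]
  expect_true(which.max(row) %in% which(fat_windows))
  expect_gt(max(row[fat_windows]), 0)

  # typical population against its own mean deviates ~0
  dev0 <- mean_spectral_deviation(rep(1L, n_samples(typ_pp)), typ_pp,
                                  typ_mean)
  expect_lt(max(abs(dev0)), 1e-12)

  # merged-cluster deviation is the size-weighted mean of its parts
  l <- fx$gmm$labels
  a <- sort(unique(l))[1:2]
  merged <- ifelse(l %in% a, -1L, l)
  devm <- mean_spectral_deviation(merged, fx$atyp, typ_mean)
  n1 <- sum(l == a[1L]); n2 <- sum(l == a[2L])
  expect_equal(devm["-1", ],
               (n1 * dev[as.character(a[1L]), ] +
                  n2 * dev[as.character(a[2L]), ]) / (n1 + n2),
               tolerance = 1e-12)
})

test_that("report tables are row-order invariant and write cleanly", {
  fx <- study_small()
  perm <- rev(seq_len(n_samples(fx$atyp)))
  r1 <- cluster_report(fx$gmm$labels, fx$atyp, fx$study$set$meta,
                       colMeans(fx$pp$absorbance))
  r2 <- cluster_report(fx$gmm$labels[perm], fx$atyp[perm],
                       fx$study$set$meta, colMeans(fx$pp$absorbance))
  expect_equal(r2$sizes, r1$sizes)
  expect_equal(r2$farms, r1$farms)
  expect_equal(r2$deviation, r1$deviation)
  d <- withr::local_tempdir()
  write_report(r1, d)
  expect_setequal(list.files(d),
                  c("sizes.csv", "farms.csv", "temporal.csv",
                    "temporal_concentration.csv", "composition.csv",
                    "composition_reference.csv", "deviation.csv"))
})
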