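test_that("transmission to absorbance follows Beer-Lambert decades", {
  expect_equal(transmission_to_absorbance(1.0), 0.0)
  expect_equal(transmission_to_absorbance(0.1), 1.0)
  expect_equal(transmission_to_absorbance(0.01), 2.0)
  expect_error(transmission_to_absorbance(0), "domain error")
  expect_error(transmission_to_absorbance(-0.5), "domain error")
})

test_that("typical spectra have the expected shape and are deterministic", {
  s1 <- generate_typical(5L, tiny_config(), seed = 1L)
  expect_equal(dim(s1$absorbance), c(5L, 1060L))
  expect_true(all(diff(s1$grid) < 0))
  s2 <- generate_typical(5L, tiny_config(), seed = 1L)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_identical(s1$meta, s2$meta)
  s3 <- generate_typical(5L, tiny_config(), seed = 2L)
  expect_false(identical(s1$absorbance, s3$absorbance))
})

test_that("metadata analytes drive their absorbance bands", {
  set <- fixture("typical_1k", function() {
    generate_typical(1000L, sim_config(), seed = 42L)
  })
  in_band <- function(lo, hi) rowMeans(set$absorbance[, set$grid >= lo &
                                                        set$grid <= hi])
  expect_gt(cor(set$meta$fat, in_band(1730, 1770)), 0.9)
  expect_gt(cor(set$meta$protein, in_band(1520, 1560)), 0.9)
  expect_gt(cor(set$meta$lactose, in_band(1020, 1060)), 0.9)
})

test_that("archetype signatures match their field descriptions", {
  cfg <- tiny_config()
  typ <- typical_small()
  water <- generate_atypical("EXTRANEOUS_WATER", 50L, cfg, seed = 2L)
  expect_lt(mean(water$meta$protein), mean(typ$meta$protein))
  expect_lt(mean(water$meta$lactose), mean(typ$meta$lactose))
  expect_gt(mean(water$meta$freezing_point), mean(typ$meta$freezing_point))

  fat <- generate_atypical("HIGH_FAT", 50L, cfg, seed = 2L)
  expect_lte(max(fat$meta$fat), 22)
  expect_gt(min(fat$meta$fat), quantile(typ$meta$fat, 0.99))

  ffa <- generate_atypical("HIGH_FFA", 50L, cfg, seed = 2L)
  expect_gte(min(ffa$meta$milk_fat_acidity),
             3 * mean(typ$meta$milk_fat_acidity))

  pc <- generate_atypical("PROTEIN_CARB_ADULTERATION", 50L, cfg, seed = 2L)
  expect_gt(mean(pc$meta$protein), mean(typ$meta$protein))
  expect_lt(mean(pc$meta$freezing_point), mean(typ$meta$freezing_point))

  expect_error(generate_atypical("NOT_A_THING", 5L, cfg), "config error")
})

test_that("fringe events sit on one instrument within two days", {
  fr <- generate_atypical("INSTRUMENT_FRINGE", 40L, tiny_config(),
                          seed = 3L)
  d <- as.Date(fr$meta$timestamp, tz = "UTC")
  expect_gte(max(vapply(unique(d), function(d0) {
    mean(d >= d0 & d < d0 + 2L)
  }, numeric(1L))), 0.99)
  tab <- sort(table(fr$meta$instrument_id), decreasing = TRUE)
  expect_gte(tab[[1L]], 38L)  # all but two on a single instrument
})

test_that("grazing archetypes land in their calendar months", {
  cfg <- sim_config(n_farms = 40L, monthly_volume = 400L, seed = 99L)
  on <- generate_atypical("GRAZING_ONSET", 30L, cfg, seed = 5L)
  expect_true(all(format(on$meta$timestamp, "%m") %in% c("04", "05")))
  off <- generate_atypical("GRAZING_END", 30L, cfg, seed = 5L)
  expect_true(all(format(off$meta$timestamp, "%m") %in% c("11", "12")))
  expect_equal(mean(on$meta$fat), 4.4, tolerance = 0.1)  # fat unchanged
})

test_that("study generation honours volume, prevalence and determinism", {
  cfg <- sim_config(n_farms = 30L, monthly_volume = 500L,
                    atypical_prevalence = 0.004,
                    date_start = "2018-01-01", date_end = "2018-04-30",
                    seed = 13L)
  st <- generate_study(cfg, seed = 13L)
  expect_equal(n_samples(st$set), 2000L)
  expect_equal(sum(st$truth$truth_label != "typical"),
               4L * round(0.004 * 500))
  expect_setequal(st$truth$sample_id, st$set$meta$sample_id)

  st2 <- generate_study(cfg, seed = 13L)
  expect_identical(st$truth, st2$truth)

  cfg0 <- sim_config(n_farms = 30L, monthly_volume = 200L,
                     atypical_prevalence = 0,
                     date_start = "2018-01-01", date_end = "2018-02-28")
  st0 <- generate_study(cfg0, seed = 1L)
  expect_true(all(st0$truth$truth_label == "typical"))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_instruments = 0L), "config error")
  expect_error(sim_config(atypical_prevalence = 0.2), "config error")
  expect_error(sim_config(archetype_mix = c(HIGH_FAT = 0.5)), "sum to 1")
  cfg <- sim_config(archetype_mix = NULL, atypical_prevalence = 0.01,
                    monthly_volume = 200L)
  expect_error(generate_study(cfg, seed = 1L), "empty archetype_mix")
})
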