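#' Convert transmission to absorbance
#'
#' `A = -log10(T)`; strictly decreasing in transmission.
#'
#' @param transmission fraction(s) in (0, 1].
#' @return Absorbance (unitless).
#' @export
transmission_to_absorbance <- function(transmission) {
  if (any(!is.finite(transmission)) || any(transmission <= 0)) {
    stop("domain error: transmission must be > 0")
  }
  -log10(transmission)
}

ARCHETYPES <- c("HIGH_FAT", "EXTRANEOUS_WATER", "HIGH_FFA",
                "PROTEIN_CARB_ADULTERATION", "INSTRUMENT_FRINGE",
                "GRAZING_ONSET", "GRAZING_END", "GENERIC")

#' Simulation configuration
#'
#' Defaults describe a one-year Dutch bulk-milk screening scenario: 400
#' farms on 4 instruments, 5000 samples/month, an atypical prevalence of
#' 0.1 percent, and an archetype mix spanning the known causes of
#' atypical spectra (sampling/fat, extraneous water, lipolysis, milk
#' adulteration, instrument fringes and grazing transitions). Composition
#' means follow Dutch bulk-milk norms (fat 4.4, protein 3.6, lactose 4.5
#' percent m/m, freezing point about -0.52 degC).
#'
#' @param n_farms number of farms.
#' @param n_instruments number of FT-IR instruments (default 4).
#' @param date_start,date_end study period (inclusive month range).
#' @param monthly_volume samples per calendar month.
#' @param atypical_prevalence fraction of samples that are atypical, in
#'   (0, 0.05].
#' @param archetype_mix named fractions over [ARCHETYPES] summing to 1.
#' @param noise_sd i.i.d. absorbance noise standard deviation.
#' @param n_latent_factors number of broad smooth latent variation
#'   factors beyond composition/season/farm/instrument.
#' @param seed integer seed used for config-level randomness (farm
#'   effects are derived from it so farms are stable across batches).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_farms = 400L,
                       n_instruments = 4L,
                       date_start = "2018-01-01",
                       date_end = "2018-12-31",
                       monthly_volume = 5000L,
                       atypical_prevalence = 0.001,
                       archetype_mix = c(
                         HIGH_FAT = 0.18, EXTRANEOUS_WATER = 0.22,
                         HIGH_FFA = 0.15, PROTEIN_CARB_ADULTERATION = 0.10,
                         INSTRUMENT_FRINGE = 0.08, GRAZING_ONSET = 0.15,
                         GRAZING_END = 0.12),
                       noise_sd = 2e-5,
                       n_latent_factors = 4L,
                       seed = 1L) {
  if (n_instruments < 1L) stop("config error: n_instruments < 1")
  if (n_farms < 1L) stop("config error: n_farms < 1")
  if (!is.null(archetype_mix)) {
    unknown <- setdiff(names(archetype_mix), ARCHETYPES)
    if (length(unknown)) {
      stop("config error: unknown archetype(s): ",
           paste(unknown, collapse = ", "))
    }
    if (length(archetype_mix) &&
        abs(sum(archetype_mix) - 1) > 1e-8) {
      stop("config error: archetype_mix must sum to 1")
    }
  }
  if (atypical_prevalence < 0 || atypical_prevalence > 0.05) {
    stop("config error: atypical_prevalence must be in [0, 0.05]")
  }
  structure(list(
    n_farms = as.integer(n_farms),
    n_instruments = as.integer(n_instruments),
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    monthly_volume = as.integer(monthly_volume),
    atypical_prevalence = atypical_prevalence,
    archetype_mix = archetype_mix,
    noise_sd = noise_sd,
    n_latent_factors = as.integer(n_latent_factors),
    seed = as.integer(seed)
  ), class = "sim_config")
}

gaussian_band <- function(wn, center, width) {
  exp(-0.5 * ((wn - center) / width)^2)
}

# Fixed spectral templates. The shapes are synthetic (smooth Gaussian
# bands at the field's canonical band centres plus broad periodic
# variation factors); amplitudes were tuned once so that preprocessed
# typical spectra satisfy the package's PCA variance calibration targets
# (16 components >= 95%, 24 components >= 99.5% on atypicals) and are
# frozen here as defaults.
sim_templates <- function(grid, config) {
  g <- function(c, w) gaussian_band(grid, c, w)
  u <- (grid - mean(grid)) / (diff(range(grid)) / 2)  # [-1, 1]
  baseline <- 1.1 * g(3350, 420) + 0.45 * g(1640, 120) +
    0.12 * g(2120, 160) + 0.06 - 0.02 * u
  loadings <- list(
    # per unit analyte (percent m/m; urea mg/100g; mfa mmol/100g fat)
    fat = 0.013 * g(1745, 16) + 0.010 * g(2855, 22) +
      0.007 * g(2925, 18) + 0.004 * g(1160, 25),
    protein = 0.020 * g(1548, 28) + 0.008 * g(1240, 30),
    lactose = 0.032 * g(1040, 28) + 0.012 * g(1075, 22) +
      0.006 * g(1150, 25),
    urea = 1.5e-4 * g(1465, 20) + 1.0e-4 * g(1160, 30),
    milk_fat_acidity = 0.012 * g(1712, 12),
    season = 1.5e-3 * (g(2850, 60) - 0.5 * g(1745, 40)),
    farm1 = 1.2e-3 * g(1300, 120),
    farm2 = 1.2e-3 * g(2780, 90)
  )
  n_lat <- config$n_latent_factors
  periods <- rep(c(320, 480, 730, 1100, 260, 610), length.out = max(n_lat, 1L))
  latent <- lapply(seq_len(n_lat), function(j) {
    6e-4 * sin(2 * pi * grid / periods[j] + 0.5 * j)
  })
  instruments <- lapply(seq_len(config$n_instruments), function(k) {
    2e-4 * sin(2 * pi * grid / (550 + 60 * k) + 0.7 * k)
  })
  # archetype-only templates
  arch <- list(
    pc_anomaly = g(2800, 15) - g(2900, 20),
    graze_shift = g(2845, 12) - g(2885, 12),
    graze_end_extra = g(1755, 10),
    generic1 = g(1325, 40) - 0.6 * g(1500, 30),
    generic2 = g(2760, 25) - 0.5 * g(1080, 35)
  )
  list(baseline = baseline, loadings = loadings, latent = latent,
       instruments = instruments, arch = arch)
}

# config-level farm random effects, stable across batches for a given
# config seed: composition intercepts + two spectral factor coefficients
farm_effects <- function(config) {
  with_seed(config$seed * 7L + 13L, {
    nf <- config$n_farms
    data.frame(
      farm_id = sprintf("F%04d", seq_len(nf)),
      fat = stats::rnorm(nf, 0, 0.12),
      protein = stats::rnorm(nf, 0, 0.07),
      lactose = stats::rnorm(nf, 0, 0.05),
      urea = stats::rnorm(nf, 0, 2.5),
      spec1 = stats::rnorm(nf), spec2 = stats::rnorm(nf),
      stringsAsFactors = FALSE
    )
  })
}

day_of_year <- function(t) as.integer(format(t, "%j"))

#' Generate typical milk spectra
#'
#' Each spectrum is a fixed milk baseline plus composition-weighted band
#' templates (fat near 1745/2855, protein near 1548, lactose near 1040
#' cm^-1, and smaller urea / free-fatty-acid bands), a seasonal factor,
#' farm and instrument effects, broad smooth latent variation, and i.i.d.
#' noise. The metadata analytes are exactly the latent values that
#' weighted the bands.
#'
#' @param n number of spectra.
#' @param config a [sim_config()].
#' @param seed integer seed for this batch.
#' @param timestamps optional POSIXct vector (length `n`) overriding the
#'   uniform draw over the config date range.
#' @return A [spectrum_set()].
#' @export
generate_typical <- function(n, config = sim_config(), seed = config$seed,
                             timestamps = NULL) {
  stopifnot(n >= 1L)
  grid <- default_wavenumber_grid()
  tpl <- sim_templates(grid, config)
  fe <- farm_effects(config)
  with_seed(seed, {
    if (is.null(timestamps)) {
      t0 <- as.numeric(as.POSIXct(config$date_start, tz = "UTC"))
      t1 <- as.numeric(as.POSIXct(config$date_end, tz = "UTC")) + 86399
      timestamps <- as.POSIXct(stats::runif(n, t0, t1),
                               origin = "1970-01-01", tz = "UTC")
    }
    farm_idx <- sample.int(config$n_farms, n, replace = TRUE)
    inst_idx <- sample.int(config$n_instruments, n, replace = TRUE)
    doy <- day_of_year(timestamps)
    season <- cos(2 * pi * (doy - 15) / 365.25)
    fat <- 4.40 + 0.18 * season + fe$fat[farm_idx] + stats::rnorm(n, 0, 0.22)
    protein <- 3.60 + 0.08 * season + fe$protein[farm_idx] +
      stats::rnorm(n, 0, 0.12)
    lactose <- 4.50 + fe$lactose[farm_idx] + stats::rnorm(n, 0, 0.07)
    urea <- 23 + fe$urea[farm_idx] + stats::rnorm(n, 0, 3)
    fp <- -0.522 - 0.003 * (lactose - 4.5) - 2e-4 * (urea - 23) / 3 +
      stats::rnorm(n, 0, 0.0025)
    mfa <- pmax(0.2, 0.45 + stats::rnorm(n, 0, 0.07))
    W <- cbind(fat, protein, lactose, urea, mfa, season,
               fe$spec1[farm_idx], fe$spec2[farm_idx])
    Tm <- cbind(tpl$loadings$fat, tpl$loadings$protein,
                tpl$loadings$lactose, tpl$loadings$urea,
                tpl$loadings$milk_fat_acidity, tpl$loadings$season,
                tpl$loadings$farm1, tpl$loadings$farm2)
    if (config$n_latent_factors > 0L) {
      Z <- matrix(stats::rnorm(n * config$n_latent_factors), nrow = n)
      W <- cbind(W, Z)
      Tm <- cbind(Tm, do.call(cbind, tpl$latent))
    }
    A <- W %*% t(Tm)
    A <- sweep(A, 2L, tpl$baseline, "+")
    inst_off <- do.call(rbind, tpl$instruments)
    A <- A + inst_off[inst_idx, , drop = FALSE]
    # broad baseline drift (offset + tilt), sample-specific
    u <- (grid - mean(grid)) / (diff(range(grid)) / 2)
    A <- A + stats::rnorm(n, 0, 1.5e-4) +
      stats::rnorm(n, 0, 1.5e-4) %o% u
    A <- A + matrix(stats::rnorm(n * length(grid), 0, config$noise_sd),
                    nrow = n)
    meta <- data.frame(
      sample_id = sprintf("S%08d", seq_len(n)),
      farm_id = fe$farm_id[farm_idx],
      instrument_id = sprintf("I%d", inst_idx),
      timestamp = timestamps,
      fat = fat, protein = protein, lactose = lactose, urea = urea,
      freezing_point = fp, milk_fat_acidity = mfa,
      stringsAsFactors = FALSE
    )
    spectrum_set(A, meta, grid)
  })
}

#' Generate atypical milk spectra of a given archetype
#'
#' Applies a documented deterministic signature on top of typical
#' spectra. See the package vignette for the magnitude choices; only the
#' 22 percent fat ceiling is externally anchored.
#'
#' @param archetype one of `ARCHETYPES`.
#' @inheritParams generate_typical
#' @return A [spectrum_set()] with modified metadata and absorbance.
#' @export
generate_atypical <- function(archetype, n, config = sim_config(),
                              seed = config$seed, timestamps = NULL) {
  if (!archetype %in% ARCHETYPES) {
    stop("config error: unknown archetype '", archetype, "'")
  }
  stopifnot(n >= 1L)
  base <- generate_typical(n, config, seed = seed, timestamps = timestamps)
  grid <- base$grid
  tpl <- sim_templates(grid, config)
  with_seed(seed * 31L + 7L, {
    A <- base$absorbance
    meta <- base$meta
    add_load <- function(delta, template) A + delta %o% template
    if (archetype == "HIGH_FAT") {
      new_fat <- stats::runif(n, 12, 22)
      A <- add_load(new_fat - meta$fat, tpl$loadings$fat)
      meta$fat <- new_fat
    } else if (archetype == "EXTRANEOUS_WATER") {
      d <- stats::runif(n, 0.20, 0.35)
      for (an in c("fat", "protein", "lactose", "urea")) {
        delta <- meta[[an]] * (1 - d) - meta[[an]]
        A <- add_load(delta, tpl$loadings[[an]])
        meta[[an]] <- meta[[an]] * (1 - d)
      }
      meta$freezing_point <- meta$freezing_point * (1 - d)  # toward 0
    } else if (archetype == "HIGH_FFA") {
      new_mfa <- stats::runif(n, 1.8, 3.0)
      A <- add_load(new_mfa - meta$milk_fat_acidity,
                    tpl$loadings$milk_fat_acidity)
      meta$milk_fat_acidity <- new_mfa
    } else if (archetype == "PROTEIN_CARB_ADULTERATION") {
      dp <- stats::runif(n, 0.8, 2.0)
      dl <- stats::runif(n, 0.5, 1.5)
      A <- add_load(dp, tpl$loadings$protein)
      A <- add_load(dl, tpl$loadings$lactose)
      A <- add_load(stats::runif(n, 0.015, 0.025), tpl$arch$pc_anomaly)
      meta$protein <- meta$protein + dp
      meta$lactose <- meta$lactose + dl
      meta$freezing_point <- meta$freezing_point - stats::runif(n, 0.02, 0.05)
    } else if (archetype == "INSTRUMENT_FRINGE") {
      # one event: shared phase, one instrument (all but two samples),
      # timestamps inside a single two-consecutive-day window
      # one shared phase per event; amplitude 50x the noise floor (1e-3 absorbance), the
      # scale at which cell-interference fringes are visibly distinct
      # from detector noise in routine absorbance spectra
      phase <- stats::runif(1, 0, 2 * pi)
      ripple <- 50 * config$noise_sd * sin(2 * pi * grid / 100 + phase)
      A <- A + matrix(ripple, nrow = n, ncol = length(grid), byrow = TRUE)
      inst <- sprintf("I%d", sample.int(config$n_instruments, 1L))
      keep_other <- if (n >= 3L) sample.int(n, 2L) else integer(0)
      meta$instrument_id[-keep_other] <- inst
      if (length(keep_other) == 0L) meta$instrument_id[] <- inst
      if (is.null(timestamps)) {
        # window starts at a day boundary so the event spans exactly two
        # calendar days
        days <- seq(as.Date(config$date_start),
                    max(as.Date(config$date_end) - 1L,
                        as.Date(config$date_start)), by = "day")
        w0 <- as.numeric(as.POSIXct(days[sample.int(length(days), 1L)],
                                    tz = "UTC"))
        meta$timestamp <- as.POSIXct(w0 + stats::runif(n, 0, 2 * 86400 - 1),
                                     origin = "1970-01-01", tz = "UTC")
      }
    } else if (archetype %in% c("GRAZING_ONSET", "GRAZING_END")) {
      sgn <- if (archetype == "GRAZING_ONSET") 1 else -1
      amp <- stats::runif(n, 0.015, 0.025)
      A <- add_load(sgn * amp, tpl$arch$graze_shift)
      if (archetype == "GRAZING_END") {
        A <- add_load(0.5 * amp, tpl$arch$graze_end_extra)
      }
      if (is.null(timestamps)) {
        months <- if (archetype == "GRAZING_ONSET") c(4L, 5L) else c(11L, 12L)
        meta$timestamp <- random_times_in_months(n, config, months)
      }
    } else if (archetype == "GENERIC") {
      A <- add_load(stats::rnorm(n, 0, 0.008), tpl$arch$generic1)
      A <- add_load(stats::rnorm(n, 0, 0.008), tpl$arch$generic2)
    }
    spectrum_set(A, meta, grid)
  })
}

# uniform timestamps restricted to given calendar months of the config
# period (falls back to the first study year if the months are absent)
random_times_in_months <- function(n, config, months) {
  seq_months <- month_sequence(config$date_start, config$date_end)
  ok <- seq_months[as.integer(format(seq_months, "%m")) %in% months]
  if (!length(ok)) ok <- seq_months
  pick <- ok[sample.int(length(ok), n, replace = TRUE)]
  starts <- as.numeric(as.POSIXct(pick, tz = "UTC"))
  lens <- as.numeric(as.POSIXct(next_month(pick), tz = "UTC")) - starts
  as.POSIXct(starts + stats::runif(n, 0, lens - 1),
             origin = "1970-01-01", tz = "UTC")
}

month_sequence <- function(from, to) {
  seq(as.Date(cut(as.Date(from), "month")), as.Date(to), by = "month")
}

next_month <- function(d) {
  as.Date(vapply(d, function(x) as.character(seq(x, by = "month",
                                                 length.out = 2L)[2L]),
                 character(1L)))
}

#' Bind spectrum sets by row
#'
#' @param sets list of `spectrum_set`s on identical grids.
#' @return One combined `spectrum_set`.
#' @export
bind_spectra <- function(sets) {
  stopifnot(length(sets) >= 1L)
  grid <- sets[[1L]]$grid
  for (s in sets) {
    if (length(s$grid) != length(grid) || any(abs(s$grid - grid) > 1e-6)) {
      stop("shape error: grids differ across sets")
    }
  }
  spectrum_set(do.call(rbind, lapply(sets, `[[`, "absorbance")),
               do.call(rbind, lapply(sets, `[[`, "meta")), grid,
               band_id = sets[[1L]]$band_id)
}

#' Generate a full synthetic screening study
#'
#' For every calendar month in the config range, `monthly_volume` samples
#' are generated of which `round(prevalence * monthly_volume)` are
#' replaced by archetype draws according to `archetype_mix`. Seasonal
#' archetypes are placed in their calendar months (grazing onset
#' April/May, grazing end November/December) and the instrument-fringe
#' archetype forms a single two-consecutive-day event on one instrument
#' within one host month. Ground truth lives only in the `truth` sidecar.
#'
#' @param config a [sim_config()]; the date range must span >= 2 months.
#' @param seed integer seed.
#' @return List with `set` (a [spectrum_set()], rows shuffled) and
#'   `truth` (data.frame `sample_id`, `truth_label`).
#' @export
generate_study <- function(config = sim_config(), seed = config$seed) {
  months <- month_sequence(config$date_start, config$date_end)
  if (length(months) < 2L) stop("config error: date range must span >= 2 months")
  k_m <- rep(round(config$atypical_prevalence * config$monthly_volume),
             length(months))
  total_atyp <- sum(k_m)
  mix <- config$archetype_mix
  if (total_atyp > 0L && (is.null(mix) || !length(mix))) {
    stop("config error: empty archetype_mix with positive prevalence")
  }
  plan <- plan_archetypes(months, k_m, mix, seed)
  sets <- vector("list", 0L)
  truth <- vector("list", 0L)
  id_counter <- 0L
  for (i in seq_along(months)) {
    m0 <- months[i]
    m1 <- next_month(m0)
    n_atyp <- if (total_atyp > 0L) sum(plan$month == i) else 0L
    n_typ <- config$monthly_volume - n_atyp
    month_cfg <- config
    month_cfg$date_start <- m0
    month_cfg$date_end <- m1 - 1L
    ts_typ <- with_seed(seed + 211L * i, {
      t0 <- as.numeric(as.POSIXct(m0, tz = "UTC"))
      t1 <- as.numeric(as.POSIXct(m1, tz = "UTC"))
      as.POSIXct(stats::runif(n_typ, t0, t1 - 1),
                 origin = "1970-01-01", tz = "UTC")
    })
    typ <- generate_typical(n_typ, config, seed = seed + 977L * i,
                            timestamps = ts_typ)
    typ$meta$sample_id <- sprintf("S%08d", id_counter + seq_len(n_typ))
    id_counter <- id_counter + n_typ
    sets[[length(sets) + 1L]] <- typ
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = typ$meta$sample_id, truth_label = "typical",
      stringsAsFactors = FALSE)
    if (n_atyp > 0L) {
      for (arch in unique(plan$archetype[plan$month == i])) {
        n_a <- sum(plan$month == i & plan$archetype == arch)
        cfg_a <- config
        if (arch == "INSTRUMENT_FRINGE") {
          # confine the fringe event window to the host month
          cfg_a$date_start <- m0
          cfg_a$date_end <- m1 - 1L
          ts <- NULL
        } else {
          # in-month timestamps; slot planning already restricted the
          # seasonal archetypes to their calendar months
          ts <- with_seed(seed + 389L * i + match(arch, ARCHETYPES), {
            t0 <- as.numeric(as.POSIXct(m0, tz = "UTC"))
            t1 <- as.numeric(as.POSIXct(m1, tz = "UTC"))
            as.POSIXct(stats::runif(n_a, t0, t1 - 1),
                       origin = "1970-01-01", tz = "UTC")
          })
        }
        at <- generate_atypical(arch, n_a, cfg_a,
                                seed = seed + 389L * i +
                                  match(arch, ARCHETYPES),
                                timestamps = ts)
        at$meta$sample_id <- sprintf("S%08d", id_counter + seq_len(n_a))
        id_counter <- id_counter + n_a
        sets[[length(sets) + 1L]] <- at
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = at$meta$sample_id, truth_label = arch,
          stringsAsFactors = FALSE)
      }
    }
  }
  set <- bind_spectra(sets)
  truth <- do.call(rbind, truth)
  perm <- with_seed(seed + 5L, sample.int(n_samples(set)))
  set <- set[perm]
  list(set = set, truth = truth[match(set$meta$sample_id,
                                      truth$sample_id), , drop = FALSE])
}

# allocate archetype draws to month slots, honouring calendar
# constraints; returns data.frame(month_index, archetype)
plan_archetypes <- function(months, k_m, mix, seed) {
  total <- sum(k_m)
  if (total == 0L) {
    return(data.frame(month = integer(0), archetype = character(0)))
  }
  counts <- largest_remainder(mix * total)
  names(counts) <- names(mix)
  counts <- counts[counts > 0L]
  month_no <- as.integer(format(months, "%m"))
  slots_left <- k_m
  plan_month <- integer(0)
  plan_arch <- character(0)
  assign_slots <- function(arch, n_needed, allowed_idx) {
    taken <- integer(0)
    # preferred (calendar-compatible) months first, then any open slot:
    # short study ranges cannot always honour seasonality
    for (idx in c(allowed_idx,
                  setdiff(sample(seq_along(months)), allowed_idx))) {
      if (n_needed <= 0L) break
      take <- min(slots_left[idx], n_needed)
      if (take > 0L) {
        slots_left[idx] <<- slots_left[idx] - take
        taken <- c(taken, rep(idx, take))
        n_needed <- n_needed - take
      }
    }
    if (n_needed > 0L) {
      stop("config error: cannot place ", n_needed, " '", arch,
           "' draws: no atypical slots left")
    }
    plan_month <<- c(plan_month, taken)
    plan_arch <<- c(plan_arch, rep(arch, length(taken)))
  }
  cnt <- function(a) if (a %in% names(counts)) counts[[a]] else 0L
  with_seed(seed + 17L, {
    nf <- cnt("INSTRUMENT_FRINGE")
    if (nf > 0L) {
      pref <- which(!month_no %in% c(4L, 5L, 11L, 12L) & slots_left >= nf)
      if (!length(pref)) pref <- which(slots_left >= nf)
      if (!length(pref)) {
        stop("config error: fringe draws (", nf,
             ") exceed any single month's atypical slots")
      }
      host <- pref[sample.int(length(pref), 1L)]
      assign_slots("INSTRUMENT_FRINGE", nf, host)
    }
    if (cnt("GRAZING_ONSET") > 0L) {
      assign_slots("GRAZING_ONSET", cnt("GRAZING_ONSET"),
                   sample(which(month_no %in% c(4L, 5L))))
    }
    if (cnt("GRAZING_END") > 0L) {
      assign_slots("GRAZING_END", cnt("GRAZING_END"),
                   sample(which(month_no %in% c(11L, 12L))))
    }
    rest <- setdiff(names(counts),
                    c("INSTRUMENT_FRINGE", "GRAZING_ONSET", "GRAZING_END"))
    # deal remaining archetypes over remaining slots in random order
    pool <- unlist(lapply(rest, function(a) rep(a, counts[[a]])))
    pool <- pool[sample.int(length(pool))]
    open <- rep(seq_along(months), slots_left)
    open <- open[sample.int(length(open))]
    if (length(pool) > length(open)) {
      stop("config error: not enough unconstrained slots for archetype mix")
    }
    plan_month <- c(plan_month, open[seq_along(pool)])
    plan_arch <- c(plan_arch, pool)
    data.frame(month = plan_month, archetype = plan_arch,
               stringsAsFactors = FALSE)
  })
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x))) - sum(fl)
  if (rem > 0L) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}
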