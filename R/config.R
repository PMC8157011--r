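#' Default pipeline configuration
#'
#' Nested key/value sections per stage, mirroring every tunable
#' hyperparameter with the screening method's values as defaults.
#' User configs are JSON files merged over these defaults.
#'
#' @return Nested list of stage settings.
#' @export
default_config <- function() {
  list(
    simulate = list(
      n_farms = 400L, n_instruments = 4L,
      date_start = "2018-01-01", date_end = "2018-12-31",
      monthly_volume = 5000L, atypical_prevalence = 0.001,
      archetype_mix = list(
        HIGH_FAT = 0.18, EXTRANEOUS_WATER = 0.22, HIGH_FFA = 0.15,
        PROTEIN_CARB_ADULTERATION = 0.10, INSTRUMENT_FRINGE = 0.08,
        GRAZING_ONSET = 0.15, GRAZING_END = 0.12),
      noise_sd = 2e-5, n_latent_factors = 4L
    ),
    preprocess = list(
      bands = list(c(925, 1600), c(1690, 1900), c(2700, 2971)),
      derivative = list(method = "finite_difference", window = 7L,
                        order = 2L)
    ),
    screen = list(
      n_components = 16L, trim_fraction = 0.001, n_iterations = 2L,
      freezing_point_lower_pct = 1, freezing_point_upper_pct = 99,
      prevalence = 0.001
    ),
    cluster = list(
      n_components = 24L, k = 7L, k_min = 4L, k_max = 20L,
      n_init = 50L, ridge = 1e-6, merge_pairs = list()
    ),
    classify = list(
      cost = c(0.1, 1, 10, 100), gamma_mult = c(0.1, 1, 10),
      cv_folds = 5L, gate_percentile = 1
    )
  )
}

#' Read a JSON config file, merged over the defaults
#'
#' @param path JSON file; missing keys fall back to [default_config()].
#' @return Nested config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_to_sim <- function(cfg, seed = 1L) {
  s <- cfg$simulate
  sim_config(
    n_farms = s$n_farms, n_instruments = s$n_instruments,
    date_start = s$date_start, date_end = s$date_end,
    monthly_volume = s$monthly_volume,
    atypical_prevalence = s$atypical_prevalence,
    archetype_mix = unlist(s$archetype_mix),
    noise_sd = s$noise_sd, n_latent_factors = s$n_latent_factors,
    seed = seed
  )
}

config_bands <- function(cfg) {
  band_selection(cfg$preprocess$bands)
}
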