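# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_config <- function(...) {
  sim_config(n_farms = 40L, monthly_volume = 400L,
             date_start = "2018-01-01", date_end = "2018-06-30",
             atypical_prevalence = 0.005, seed = 99L, ...)
}

# 300 typical spectra, raw grid
typical_small <- function() {
  fixture("typical_small", function() {
    generate_typical(300L, tiny_config(), seed = 11L)
  })
}

# preprocessed version plus a fitted screening model
screen_fixture <- function() {
  fixture("screen_fixture", function() {
    set <- generate_typical(1000L, tiny_config(), seed = 21L)
    pp <- preprocess_spectra(set)
    model <- fit_screening_model(pp)
    list(raw = set, pp = pp, model = model)
  })
}

# well-separated latent blobs for GMM/classifier tests
blob_latent <- function(n_per = 15L, k = 10L, d = 24L, sep = 12,
                        seed = 5L) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d)
  centers <- sep * centers / sqrt(rowSums(centers^2))
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d, 0, 0.5), n_per, d), 2L,
          centers[i, ], "+")
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# small end-to-end study shared by cluster/classify/report tests
study_small <- function() {
  fixture("study_small", function() {
    cfg <- sim_config(n_farms = 80L, monthly_volume = 1500L,
                      atypical_prevalence = 0.005, seed = 7L)
    study <- generate_study(cfg, seed = 7L)
    pp <- preprocess_spectra(study$set)
    model <- fit_screening_model(filter_freezing_point(pp))
    scores <- flag_monthly(anomaly_scores(pp, model), 0.005)
    atyp <- pp[pp$meta$sample_id %in% scores$sample_id[scores$flagged]]
    truth <- study$truth$truth_label[match(atyp$meta$sample_id,
                                           study$truth$sample_id)]
    lf <- fit_cluster_latent(atyp)
    latent <- cluster_latent(atyp, lf)
    gmm <- fit_gmm(latent, K = 7L, n_init = 20L, seed = 3L)
    list(cfg = cfg, study = study, pp = pp, screen = model,
         scores = scores, atyp = atyp, truth = truth,
         latent_fit = lf, latent = latent, gmm = gmm)
  })
}

meta_stub <- function(n) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), farm_id = "F1",
             instrument_id = "I1", timestamp = "2018-06-01T00:00:00",
             fat = 4.4, protein = 3.6, lactose = 4.5, urea = 23,
             freezing_point = -0.52, milk_fat_acidity = 0.45)
}

tiny_set <- function(X, grid) spectrum_set(X, meta_stub(nrow(X)), grid)

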