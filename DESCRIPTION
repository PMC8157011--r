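Package: milkscreen
Title: Untargeted Screening and Clustering of Atypical FT-IR Milk Spectra
Version: 0.1.0
Authors@R:
    person("Milkscreen", "Developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for untargeted screening of atypical bovine milk
    Fourier-transform mid-infrared (FT-IR) spectra. Implements the full
    screening chain: chemometric preprocessing (wavenumber band selection,
    first-derivative spectra, standard and robust scaling), an anomaly
    score combining the PCA-latent Mahalanobis distance with the
    reconstruction residual, monthly prevalence-based flagging, Gaussian
    mixture model clustering of the flagged spectra with full covariance
    matrices and k-means initialised restarts, support-vector assignment
    of new atypical spectra to the discovered clusters, and cluster
    characterisation reports (sizes, compositional profiles, farm,
    instrument and temporal diagnostics). A calibrated synthetic milk
    spectrum generator makes every stage testable without proprietary
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
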