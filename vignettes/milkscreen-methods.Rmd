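---
title: "Untargeted screening of atypical FT-IR milk spectra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted screening of atypical FT-IR milk spectra: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(milkscreen)
```

## The problem

Routine FT-IR analysis of bulk milk produces a mid-infrared absorbance
spectrum per sample (here: 1060 points, 5012 down to 926 cm^-1) from
which fat, protein, lactose, urea, freezing point and milk-fat acidity
are predicted. Targeted adulteration models can only detect adulterants
they were trained on. *Untargeted* screening instead fits a fingerprint
of normal milk and flags any spectrum that deviates from it — but by
itself it cannot say *how* a spectrum is atypical. `milkscreen`
implements the combined approach: an untargeted anomaly score, monthly
prevalence-based flagging, unsupervised discovery of categories of
atypical spectra, a classifier that assigns new atypical spectra to
those categories, and characterisation reports that link each category
to composition, farm, instrument and calendar structure.

## The screening model

Preprocessing retains three informative wavenumber windows (925–1600,
1690–1900, 2700–2971 cm^-1, closed intervals; 300 of the 1060 points)
and takes a first derivative. The derivative is a central finite
difference in grid-index units, computed *within* each contiguous band
with one-sided differences at band edges, so no difference ever spans a
band gap. A Savitzky–Golay derivative would also be defensible; the
plain finite difference is the simplest faithful reading and is the
tested default. Bands are selected before differentiation (the
alternative order — differentiate the full grid, then select — differs
only at band edges).

On the preprocessed training spectra, each retained point is
standardised to zero mean and unit variance, and a 16-component PCA is
fitted (by design slightly overfitted, so that small-variance directions
that matter for atypical spectra are represented). Each spectrum then
gets two complementary statistics:

* **Mahalanobis distance** in the 16-dimensional latent space,
  `sqrt((t - mu)' P (t - mu))` — how unusual the spectrum is *within*
  the model;
* **reconstruction residual**: the RMSE between the scaled spectrum and
  its reconstruction from the 16 components — how much of the spectrum
  lies *outside* the model. The residual is computed in the
  scaled-derivative space in which the PCA operates.

Both are standardised with the training mean/SD and summed into the
**spectrum anomaly score**; training scores are centred near zero and
higher is more atypical. Two trim iterations precede the final fit:
after each full fit, the `ceiling(0.001 * n)` highest-scoring spectra
are removed, and the final model is fitted on the survivors. The score
standardisation is frozen from the final training pass: new data are
always scored against the same yardstick, which keeps scores comparable
over time.

Numerical choices that are pinned for reproducibility:

* latent precision = inverse of the latent covariance with ridge
  `1e-10 * trace / 16` on the diagonal, symmetrised;
* trim count per iteration `ceiling(fraction * n)` (guarantees at least
  one removal at small n);
* freezing-point prefilter: samples strictly outside the 1st/99th
  percentiles are removed. Percentiles use the inverse empirical CDF
  (quantile type 1): with an interpolating quantile, the strict-tail
  rule would remove the extremes of even a two-sample set, which is not
  the intended degenerate behaviour;
* PCA eigenvector signs are fixed (largest-magnitude loading positive)
  so results do not depend on the LAPACK build.

## Flagging, clustering, classification

The true prevalence of atypical milk is unknown; the pipeline assumes
0.1 % **per calendar month** and flags the `floor(0.001 * n_month)`
highest-scoring spectra of each month (ties broken by score, then
sample id). Monthly thresholding equalises flagged counts across
seasons.

Flagged spectra are centred and scaled with *robust* statistics
(median, IQR with linearly interpolated quartiles) to blunt the
influence of extreme outliers, projected onto 24 principal components
(~99.5 % of the variance on calibrated data), and clustered with
Gaussian mixture models: full covariance per component (ridge
`1e-6 * mean diagonal`, floored for single-member components), k-means
initialisation, 50 restarts with deterministically derived seeds, best
final log-likelihood wins. Restarts that lose a component are
re-initialised and counted. `sweep_k()` fits K = 4..20 and records
log-likelihood, BIC, mean silhouette and sizes — *diagnostics, not a
decision rule*: the number of clusters is a judgement call informed by
six criteria (within/between spectral similarity, sizes, unique-farm
proportion, temporal concentration, instrument distribution,
compositional profile), all emitted by `evaluate_clusters()`. The
final K and any merges are taken from configuration;
`suggest_instrument_merges()` proposes merging pairs of clusters whose
compositional profiles overlap while their instrument supports are
disjoint and jointly complete — the signature of one physical category
split in two by inter-instrument differences. Merged components are
renumbered by descending size; cluster numbers are arbitrary labels and
are not comparable across runs.

New atypical spectra are assigned by an RBF-kernel support-vector
classifier (one-vs-one, deterministic SMO) trained on the latent
representations with the final cluster labels as classes. All
transformations (median, IQR, eigenvectors) are frozen from training.
The hyperparameter grid — cost {0.1, 1, 10, 100} × kernel width
{0.1, 1, 10} × the scale heuristic `1/(d * Var(X))` — is searched with
seeded stratified 5-fold cross-validation scored by weighted F1;
classes smaller than the fold count reduce the fold count with a
warning. Because an SVM always answers, an optional GMM typicality
gate marks samples whose mixture log-density falls below a percentile
of the training densities as `unassignable` without changing the
primary label — the probabilistic-generative escape hatch for spectra
the cluster solution has outgrown.

## The synthetic world

Real bulk-milk screening archives are proprietary, so the generator
(`generate_typical()`, `generate_atypical()`, `generate_study()`)
emulates the statistical structure the method assumes. A typical
spectrum is a fixed smooth milk baseline (water-dominated) plus
composition-weighted Gaussian band templates — fat near 1745 and
2855/2925 cm^-1, protein near 1548 (amide II) and 1240, lactose near
1040/1075, urea near 1465, free fatty acids near 1712 (carbonyl) —
plus a seasonal factor, per-farm random effects (stable across batches
for a given configuration seed), four fixed instrument offset shapes,
four broad smooth latent variation factors, baseline drift, and i.i.d.
noise (`noise_sd = 2e-5` absorbance). The metadata analytes are
*exactly* the latent values that weighted the bands, so
composition-vs-band correlations are positive by construction (>0.9
over the named windows on 1000 spectra). Composition centres follow
Dutch bulk-milk norms: fat 4.4, protein 3.6, lactose 4.5 % m/m,
freezing point −0.522 °C, urea 23 mg/100 g, milk-fat acidity
0.45 mmol/100 g fat.

Band and nuisance amplitudes were tuned **once** so that two
calibration targets hold, and then frozen: 16 components explain at
least 95 % of the variance of preprocessed typical spectra, and 24
components at least 99.5 % on robust-scaled flagged spectra. They were
not revisited after acceptance measurements.

Archetypes apply documented signatures on top of typical spectra. Only
the 22 % fat ceiling is externally anchored; all other magnitudes are
the package's own choices, picked so the planted categories are
well-separated (the regime in which cluster recovery is a meaningful
test) and realistic in kind:

* `HIGH_FAT` — fat redrawn from U(12, 22) % with bands rescaled
  (insufficient mixing before sampling);
* `EXTRANEOUS_WATER` — all solutes diluted by U(0.20, 0.35), freezing
  point moved proportionally toward 0 °C;
* `HIGH_FFA` — milk-fat acidity redrawn from U(1.8, 3.0) (≥3× typical)
  with a matching 1712 cm^-1 carbonyl increase;
* `PROTEIN_CARB_ADULTERATION` — protein +U(0.8, 2.0), lactose
  +U(0.5, 1.5), freezing point −U(0.02, 0.05), plus a structural
  anomaly template in 2740–2970 cm^-1;
* `INSTRUMENT_FRINGE` — a sinusoidal ripple (period 100 cm^-1, one
  shared phase per event) at 50× the noise floor, all but two samples
  on one instrument, timestamps inside one two-calendar-day window.
  The ripple amplitude is deliberately above the noise floor:
  cell-interference fringes are visible artifacts, and at noise scale
  the planted event is not a recoverable category;
* `GRAZING_ONSET` / `GRAZING_END` — opposite-signed fatty-acid-region
  shape changes (around 2845/2885 cm^-1) without a fat change,
  timestamps in April–May / November–December;
* `GENERIC` — a random low-rank perturbation on two fixed templates
  (not part of the default mix; available for robustness experiments).

`generate_study()` plants `round(prevalence * monthly_volume)`
atypicals per month (default: 5 of 5000), allocating archetypes to
calendar-compatible months — the fringe event owns a single host month,
grazing archetypes their seasons — and falls back to any open month
when a short study range cannot honour seasonality. Ground-truth labels
live only in a sidecar table, never in the spectra file, so they cannot
leak into the pipeline under test.

What the generator does **not** emulate: real Milkoscan optics,
inter-instrument calibration transfer (the vendor's standardisation
procedure is out of scope), correlated detector noise, analyte
prediction error (metadata equal the spectral weights exactly), and
overlap between archetype categories. A green end-to-end test therefore
establishes that the chain — scoring, flagging, latent construction,
mixture fitting, classification, reporting — is implemented correctly
and recovers structure it is supposed to recover; it does not establish
detection limits on real milk.

## Default parameters at a glance

| Parameter | Default | Why |
|---|---|---|
| bands (cm^-1) | 925–1600, 1690–1900, 2700–2971 | informative, water-free windows |
| PCA components (screen) | 16 | ~95 % variance, slight overfit by design |
| trim | 0.1 % × 2 iterations | outlier-robust fingerprint |
| flagging prevalence | 0.1 %/month | assumed atypicality rate |
| PCA components (cluster) | 24 | ~99.5 % variance of flagged spectra |
| GMM | K from config, 50 restarts, full covariance, ridge 1e-6 | pinned fitting protocol |
| SVC grid | C ∈ {0.1,1,10,100}, γ ∈ {0.1,1,10}×scale | standard coverage, logged |
| noise_sd | 2e-5 absorbance | calibrated to the PCA targets |

## Known limitations

* Cluster numbering is by size, not by any substantive identity; labels
  do not transfer across datasets.
* The six cluster-evaluation criteria quantify, but do not automate,
  the choice of K; two analysts can defensibly pick different K.
* The within-cluster similarity criterion uses Euclidean distance in
  the 24-dimensional latent space; other metrics (correlation distance
  on spectra) are reasonable alternatives.
* With ~60 flagged spectra (the default study), per-cluster covariances
  in 24 dimensions are heavily ridge-dependent; conclusions about
  cluster *shape* at that scale are not meaningful, only membership.
* The temporal profile's per-cluster normalisation divides by the
  cluster's maximum weekly count; normalising by the cluster's total is
  a config-level alternative that changes the look, not the ordering.
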