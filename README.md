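# prfmap

Population receptive field (pRF) mapping for bar-sweep fMRI experiments in
which the bars are confined to a central grey "carpet" occluder — including
bars defined only by illusory (Kanizsa-type) contours or by occlusion, and
their low-contrast luminance control.  The package is aimed at visual
neuroscientists who want a fully testable, self-contained version of this
analysis: it ships the stimulus/run-design encoding, the Gaussian pRF
forward model, coarse-to-fine estimation, a ground-truth synthetic fMRI
generator, and the map-coherence statistics used to compare retinotopic
maps across stimulus conditions in V1–V3.

## The model

Each vertex's pRF is an isotropic 2-D Gaussian
g(x, y) = exp(−((x−x₀)² + (y−y₀)²) / 2σ²) in visual-field coordinates
(degrees).  The predicted BOLD series is the per-volume overlap of a binary
stimulus aperture with g, convolved with a canonical double-gamma HRF and
sampled at volume onsets, scaled by an amplitude β over a baseline.
Estimation is coarse-to-fine: a correlation sweep over a precomputed
prediction bank (x₀, y₀ ∈ [−4, 4]° step 0.25°, σ log-spaced 0.2–2.25°),
then a Nelder–Mead simplex over (x₀, y₀, log σ) maximizing R², with β and
baseline solved by least squares.  Goodness of fit R² is the squared
Pearson correlation between prediction and the detrended, z-scored,
run-averaged data.

Map-level statistics operate on the fitted tables: quadrant ROI
restriction (centres 0.75–3.0° from both cardinal axes), responsive-vertex
proportions (R² > 0.05, strict), Fisher-z-averaged correlations between
observed time courses and reference-map predictions with a vertex-shuffle
permutation test, Spearman and pairwise Fisher–Lee circular parameter
correlations between conditions, and gaze-stability MAD.

## Worked example

```r
library(prfmap)

scaf  <- prf_scaffold(build_aperture_movie())   # stimulus + design + HRF
bank  <- prediction_bank(scaf)                  # coarse search bank

## fit one noiseless vertex
y   <- predict_timeseries(prf_params(1.5, -2, 0.8, beta = 1), scaf)
fit <- prf_fit(y, scaf, bank = bank)
fit
#> Population receptive field fit
#>   centre (1.500, -2.000) deg, sigma 0.799 deg
#>   beta 0.339, baseline -0.000, R^2 1.000

## a synthetic experiment with known ground truth
truth <- sample_ground_truth(n_per_area = 20, seed = 42)
ds    <- simulate_runs(truth, scaf, seed = 42)
ds
#> Synthetic pRF dataset: 60 vertices, 4 conditions x 4 runs x 180 volumes (seed 42)

fits <- fit_prf_dataset(ds, scaf, bank = bank)
head(fits[fits$condition == "mapping",
          c("vertex_id", "area", "x0", "y0", "sigma", "r_squared")], 4)
#>   vertex_id area    x0    y0  sigma r_squared
#> 1   V1_v001   V1 -2.34  1.54 0.5301     0.444
#> 2   V1_v002   V1  1.80  2.30 0.0293     0.117
#> 3   V1_v003   V1  1.19 -2.01 1.0651     0.261
#> 4   V1_v004   V1  2.29  3.18 1.0266     0.331

round(tapply(fits$r_squared, fits$condition, median), 3)
#>   kanizsa luminance   mapping occlusion
#>     0.111     0.113     0.521     0.087
```

The high-contrast mapping condition fits far better than the illusion and
low-contrast conditions, whose gains the generator sets to a quarter of the
mapping amplitude — the regime in which map-level statistics, not
individual vertices, carry the information.  Coherence of a map against
reference predictions:

```r
v3  <- which(truth$area == "V3")
obs <- t(sapply(v3, function(v)
  preprocess_runs(do.call(rbind, lapply(ds$series$kanizsa, function(m) m[v, ])))))
permutation_test(obs, truth[v3, ], scaf, n_perm = 1000, seed = 1)
#> Vertex-shuffle permutation test: zbar = 0.3992, p = 0.000999 (1000 permutations, 20 vertices)
```

The observed Fisher-z mean correlation exceeds every prediction-shuffled
replicate: the Kanizsa-evoked map is vertex-specific, i.e. retinotopically
coherent, even though its median R² is only ~0.1.

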