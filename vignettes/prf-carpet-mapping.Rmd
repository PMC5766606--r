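---
title: "Population receptive field mapping with carpet-confined bars: model, estimation and map statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field mapping with carpet-confined bars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Visual areas V1-V3 contain retinotopic maps: each cortical location (here,
each surface *vertex*) responds to a restricted region of the visual field,
its population receptive field (pRF).  A standard way to measure these maps
is to sweep a high-contrast bar across the visual field while recording
fMRI, and to fit, per vertex, a model of where in the visual field that
vertex "looks".  A more delicate question is whether bars that are only
*implied* -- defined by illusory (Kanizsa-type) contours, or by an object
moving *behind* an occluding surface -- also produce coherent retinotopic
maps, and how those maps compare with maps evoked by a physically matched
low-contrast luminance bar.  In the experiment this package models, all
three bar types traverse the same central grey "carpet" (a square occluder
over a brick background), so they share identical geometry and differ only
in how much signal they evoke.

`prfmap` implements the full analysis pipeline for this design --
stimulus-aperture construction, Gaussian pRF forward modelling,
coarse-to-fine estimation, ROI restriction and the map-coherence statistics
-- together with a synthetic fMRI generator with known ground truth, so
every stage can be validated end to end without any scanner data.

## Forward model

The pRF of a vertex is a 2-D isotropic Gaussian with centre $(x_0, y_0)$
(degrees of visual angle) and size $\sigma$:

$$g(x, y) = \exp\!\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{2\sigma^2}\right).$$

No normalization constant is applied; absolute scale is absorbed into the
amplitude parameter $\beta$.  The stimulus is a binary aperture movie
$A_t(x, y)$ on a raster of the visual field, one frame per retained volume.
The neural drive at volume $t$ is the overlap
$d_t = \sum_{x,y} A_t(x,y)\, g(x,y)\, \Delta^2$ (cell area $\Delta^2$),
which is convolved with a haemodynamic response function $h$ and sampled at
the volume onsets:

$$\hat{s}_t = \beta \,(d * h)(t) + \text{baseline}.$$

The model is linear in $\beta$ and the baseline; those two are therefore
solved by least squares, and only $(x_0, y_0, \sigma)$ require nonlinear
search.

### Stimulus geometry

Pixel sizes are converted to visual angle with the full tangent formula
$2\arctan(s/2d)$ using the **vertical** pixel pitch (20.2 cm / 1080 px at
68 cm viewing distance).  This convention reproduces the display's printed
sizes -- occluder 6.7°, brick background 11.4°, fixation dot 0.08°, screen
height 16.9° -- whereas no simple convention reproduces the printed
horizontal extent, so horizontal conversions are not used as checks.

One run is a 10 s blank (dummy volumes, discarded) followed by six 30 s
trials: bar sweeps Right, Up, Left, Down with a blank trial after the
second and fourth sweep; TR = 1 s, so 190 volumes total, 180 retained.  The
bar is 0.9° wide and 10.9° long (it overlaps the brick by 2.1° on either
side of the 6.7° occluder).  Bar centres traverse the occluder width in 30
equal steps of 6.7/30°, the first centre half a step inside the occluder
edge; this makes a leftward sweep the exact mirror of the rightward sweep.
Because the bar is wider than one step, the swept union extends 0.9° minus
one step beyond the occluder along the motion axis -- a direct consequence
of centring the sweep on the carpet.  The bar's 2 Hz on/off flicker within
each 1 s step is ignored at raster level: at TR resolution the duty cycle
is invisible, only bar position matters.  All three stimulus conditions
share the identical aperture movie; they differ in evoked amplitude, not
geometry.

The default raster covers ±8.5° (the mapping stimulus extent) at 0.1°
cells, centre-sampled: a cell is "on" iff its centre lies inside the bar
rectangle.  At this resolution the raster overlap agrees with the separable
Gaussian closed form (products of normal CDF differences) to better than 2%
wherever the overlap amounts to at least a few percent of the Gaussian
mass, for $\sigma \ge 0.3°$; in deep tails the relative error of midpoint
quadrature grows, but the absolute error stays below 0.2% of the Gaussian
mass everywhere, which is negligible for fitting.  The un-truncated
Gaussian loses less than 1% of its mass off the grid for $\sigma \le 2°$
and eccentricity $\le 4°$.

### Haemodynamic response

The experiment's source does not state its HRF, so the package uses the
field-standard canonical double gamma: a positive lobe peaking at 6 s and
an undershoot around 16 s (dispersions 1 s, peak:undershoot ratio 6, 32 s
support, 0.1 s resolution), peak-normalized.  Each lobe is parameterized by
its mode, so `peak_delay_s` is literally the time of the kernel maximum.
Convolution runs at 0.1 s resolution with the neural drive held constant
over each TR and a zero (blank) history -- which matches the physical
situation, since each run begins with a 10 s blank.  Because drive,
convolution and sampling are all linear, the whole chain is precomputed
once as a volumes-to-volumes matrix (`prf_scaffold()`), reducing each
candidate evaluation to one matrix product.

## Estimation

Per vertex, raw runs are linearly detrended, z-scored (mean 0, sd 1) and
averaged across runs.  "Normalized" is read as per-run z-scoring;
percent-signal change would differ only by a per-run scale factor, which
the correlation-based fit ignores anyway.  Runs whose detrended signal has
zero variance are flagged and contribute zeros; blank and null-trial
volumes are retained (they constrain the baseline), only dummy volumes are
dropped.

Model predictions are passed through the same detrending projection as the
data.  This is the standard "trend nuisance regressor" treatment: without
it, a trend component present in the prediction but removed from the data
biases the fit, and noiseless recovery would not be exact.

Fitting is coarse-to-fine:

1. **Coarse**: Pearson correlation between the preprocessed series and a
   precomputed bank of unit-amplitude predictions on a search grid
   ($x_0, y_0 \in [-4, 4]°$ step 0.25°, $\sigma \in \{0.2, 0.3, 0.45,
   0.67, 1.0, 1.5, 2.25\}°$ log-spaced -- the carpet with margin, at a
   tractable bank size).  Ties resolve to the first candidate in
   $(x_0, y_0, \sigma)$ lexicographic order.
2. **Fine**: Nelder-Mead simplex over $(x_0, y_0, \log\sigma)$ maximizing
   $R^2$, the squared Pearson correlation between prediction and data;
   $\beta$ and baseline by least squares at the optimum.  The simplex runs
   with a function-value tolerance of $10^{-6}$ and at most 400
   evaluations.  The intent is convergence to about $10^{-3}$ in the
   parameters; because $R^2$ is locally quadratic around the optimum, a
   much tighter function tolerance is needed to reach that -- a value
   tolerance of $10^{-3}$ stops an order of magnitude too early.  If the
   simplex fails to improve on the coarse candidate, the coarse parameters
   are returned flagged as non-converged, so $R^2$ never decreases from
   coarse to fine.

Negative amplitudes are kept but flagged.  Polar angle
($\mathrm{atan2}(y_0, x_0)$, right horizontal meridian = 0,
counter-clockwise) and eccentricity derive from the centre; the origin maps
to polar angle 0 by convention.

On noiseless synthetic vertices this recovers centres to well under 0.05°
and $\sigma$ to well under 5%.  At the low signal-to-noise ratio typical of
illusion-evoked responses (median fitted $R^2 \approx 0.1$) the median
centre error is about 1.2°: position information at a per-vertex
correlation of $r \approx 0.3$ over 180 volumes is intrinsically scarce --
the matched-filter grid argmax itself shows the same error, and temporal
smoothing does not help -- so individual low-SNR estimates should be read
as noisy draws around the truth, which is precisely why the map-level
statistics below aggregate across vertices.

## Synthetic data

`sample_ground_truth()` draws per-area vertex tables: centres uniform over
the carpet square (±3.35°), with a configurable fraction (default 80%)
inside the quadrant analysis band so the ROI filter has work to do; sizes
uniform in 0.4-1.2° plus per-area shifts (+0.25° V2, +0.5° V3), mirroring
the V1 < V2 < V3 growth of pRF size along the hierarchy.

`simulate_runs()` runs the forward model generatively: per vertex,
condition and run, the unit prediction is scaled by condition gain × area
gain, then a linear drift (slope uniform in ±1 per run) and stationary
AR(1) Gaussian noise (lag-1 correlation 0.3, marginal sd `white_sd`) are
added; 4 runs per condition.  Default gains -- mapping 1.0, luminance 0.25,
Kanizsa 0.25, occlusion 0.20; V1 0.7, V2 1.0, V3 1.3 -- are calibration
knobs chosen to reproduce the experiment's *ordinal* findings (mapping far
above the rest; no luminance-vs-illusions offset; Kanizsa slightly above
occlusion; everything increasing V1→V3), not printed values.  `white_sd`
defaults to 8, calibrated once so that the illusion-condition median fitted
$R^2$ lands near 0.1, the low-SNR regime of interest.  All randomness flows
from one root seed through fixed per-stream offsets (truth, runs, gaze), so
a dataset is bit-reproducible from `(config, seed)`.

What the generator does **not** emulate: cortical surface geometry and
vertex adjacency, physiological (cardiac/respiratory) noise spectra,
scanner drifts beyond linear, the attention task, or between-subject
variability.  Passing tests therefore show that the *pipeline* is correct
and that its statistics behave as claimed under the assumed noise model --
they do not certify the magnitudes one would obtain on real scanner data,
which is also why group-level absolute numbers (proportions of responsive
vertices, specific F/t values) are reproduced only as ordinal patterns.

## Map statistics

- **ROI band**: analysis is restricted to vertices whose reference
  (mapping-derived) centres fall 0.75-3.0° from *both* cardinal axes
  (bounds inclusive) -- four quadrant rectangles inside the carpet that
  avoid the fixation "plus sign" and the carpet edges.
- **Responsive fraction**: share of selected vertices with $R^2$ strictly
  above 0.05.
- **Prediction correlation**: per vertex, Pearson correlation between the
  observed preprocessed series of a condition and the prediction generated
  from that vertex's reference parameters; summarized by the Fisher-z
  average $\tanh(\mathrm{mean}(\mathrm{atanh}\, r))$, with $|r|$ clipped at
  $1 - 10^{-12}$ before `atanh`.
- **Permutation test**: the observed Fisher-z mean is compared with its
  distribution over uniform re-assignments of predictions to vertices
  (default 10,000), testing whether the correlations are vertex-specific,
  i.e. whether the map as a *map* is coherent.  One-sided exceedance p with
  the add-one correction $(k+1)/(n+1)$, matching per-participant threshold
  reporting; the permutation operates within the analyzed vertex set of
  each area.  Cross-vertex correlations are precomputed once, so each
  permutation is a table lookup.
- **Parameter consistency**: per area and condition pair, Spearman rank
  correlation of each scalar parameter across vertices; polar angle uses
  the Fisher-Lee (1983) *pairwise* circular correlation
  $\sum_{i<j}\sin(a_i-a_j)\sin(b_i-b_j)$ (normalized).  The
  circular-mean-deviation variant is deliberately avoided: band-restricted
  polar angles cluster in four modes 90° apart, the resultant is near
  zero, and any statistic built on the circular mean becomes unstable
  (its sign can flip between datasets drawn from the same generator).
  Cells with fewer than 3 usable vertices are marked missing; group
  averaging of correlations goes through the Fisher z scale.
- **Gaze stability**: median absolute deviation (no consistency scaling)
  of gaze samples per axis; simulated fixation jitter (Gaussian, default
  sd 0.3°, 60 Hz) lands near $0.6745 \times 0.3 \approx 0.20°$, well below
  the 0.5° compliance bound.

## Degenerate inputs and tie-breaks

Zero-variance series are flagged, never fitted; empty ROI selections and
sub-minimum vertex counts raise errors or missing cells rather than
silently producing numbers; `(0, 0)` centres take polar angle 0; Fisher z
is clipped before `atanh`; coarse-stage correlation ties resolve
deterministically.  Fitting a dataset twice yields identical tables, and
permuting vertex order permutes the output rows correspondingly.

## Problem sizes used by the test-suite and acceptance script

Design checks run in milliseconds.  The forward-model oracle uses 100
random bar/pRF pairs.  Recovery uses 6 noiseless vertices and 300 vertices
at illusion-level SNR; the ordinal analyses use 180 vertices (60 per area)
across all four conditions; permutation validity uses 200 replicates at 500
permutations (a scaled-down null calibration) plus one 10,000-permutation
run on matched data.  These sizes keep a full run in minutes while leaving
the medians and rankings they assert stable across seeds.

## Known limitations

- Only the isotropic-Gaussian pRF with linear spatial summation is
  implemented; no compressive-summation or difference-of-Gaussians
  variants, and no per-subject HRF estimation.
- Centre estimates at median $R^2 \approx 0.1$ carry ~1° median error;
  vertex-level parameters in that regime are only meaningful in aggregate.
- The generator's gains and noise are calibrated to ordinal patterns; the
  package makes no claim of reproducing absolute group statistics from
  real data.
- Group-level repeated-measures models are out of scope; the tidy fit and
  consistency tables are designed to drop into any standard stats package.
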