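#' Noise model for simulated fMRI series
#'
#' Serially correlated Gaussian noise plus a linear scanner drift.
#' `white_sd` is the marginal (stationary) standard deviation of the
#' AR(1) process; `ar1_rho` its lag-1 autocorrelation.  The drift slope
#' is drawn uniformly in `+/- drift_slope_range` per run and spans the
#' run linearly.
#'
#' @param white_sd Marginal noise standard deviation (signal units).
#' @param ar1_rho AR(1) coefficient in `[0, 1)`.
#' @param drift_slope_range Half-range of the uniform drift excursion
#'   (signal units per run).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(white_sd = 8.0, ar1_rho = 0.3,
                        drift_slope_range = 1.0) {
  if (white_sd < 0 || ar1_rho < 0 || ar1_rho >= 1)
    stop("need white_sd >= 0 and 0 <= ar1_rho < 1", call. = FALSE)
  structure(list(white_sd = white_sd, ar1_rho = ar1_rho,
                 drift_slope_range = drift_slope_range),
            class = "noise_model")
}

# stationary AR(1) noise + linear drift for one run (uses the current RNG
# stream)
.drift_and_noise <- function(n, noise) {
  slope <- stats::runif(1, -noise$drift_slope_range, noise$drift_slope_range)
  drift <- slope * seq(-1, 1, length.out = n)
  if (noise$white_sd == 0) return(drift)
  innov_sd <- noise$white_sd * sqrt(1 - noise$ar1_rho^2)
  e <- stats::rnorm(n, sd = innov_sd)
  e[1] <- stats::rnorm(1, sd = noise$white_sd)
  drift + as.vector(stats::filter(e, noise$ar1_rho, method = "recursive",
                                  init = 0))
}

# Documented per-stream seed derivation from the one root seed: every
# consumer of randomness draws from an independent, reproducible stream.
.stream_seed <- function(seed, stream) {
  offs <- c(truth = 1L, runs = 2L, gaze = 3L)
  as.integer((as.numeric(seed) * 1009 + offs[[stream]]) %% 2147483600)
}

#' Sample a ground-truth retinotopic map
#'
#' Draws vertices for areas V1, V2 and V3 with pRF centres uniform over
#' the carpet square and sizes uniform in `sigma_range` plus a per-area
#' shift (V1 < V2 < V3, following the cortical hierarchy).  A fraction
#' `band_fraction` of centres is drawn inside the quadrant analysis band
#' (`inner`..`outer` degrees from both cardinal axes) and the rest
#' deliberately outside it, so the ROI filter has something to reject.
#'
#' @param n_per_area Vertices per area.
#' @param carpet A [carpet_spec()].
#' @param sigma_range Range of the uniform sigma draw (degrees) for V1.
#' @param seed Integer seed (deterministic output).
#' @param band_fraction Fraction of centres forced into the analysis band.
#' @param band A [roi_band()] defining that band.
#' @param area_sigma_shift Additive sigma shift per area (degrees).
#' @return Data frame with vertex_id, area, x0, y0, sigma, beta, baseline.
#' @export
sample_ground_truth <- function(n_per_area = 100, carpet = carpet_spec(),
                                sigma_range = c(0.4, 1.2), seed = 1,
                                band_fraction = 0.8, band = roi_band(),
                                area_sigma_shift = c(V1 = 0, V2 = 0.25,
                                                     V3 = 0.5)) {
  if (n_per_area <= 0) stop("n_per_area must be positive", call. = FALSE)
  if (length(sigma_range) != 2 || diff(sigma_range) < 0 || sigma_range[1] <= 0)
    stop("sigma_range must be an increasing positive pair", call. = FALSE)
  set.seed(.stream_seed(seed, "truth"))
  half <- carpet$occluder_side_deg / 2
  areas <- names(area_sigma_shift)
  n_band <- round(band_fraction * n_per_area)

  draw_coord <- function(n, in_band) {
    if (in_band) {
      sign <- sample(c(-1, 1), n, replace = TRUE)
      sign * stats::runif(n, band$inner_deg, min(band$outer_deg, half))
    } else {
      stats::runif(n, -half, half)
    }
  }
  rows <- lapply(seq_along(areas), function(a) {
    in_band <- seq_len(n_per_area) <= n_band
    x0 <- y0 <- numeric(n_per_area)
    x0[in_band] <- draw_coord(sum(in_band), TRUE)
    y0[in_band] <- draw_coord(sum(in_band), TRUE)
    # rejection-sample the rest until genuinely outside the band
    for (i in which(!in_band)) {
      repeat {
        x <- draw_coord(1, FALSE); y <- draw_coord(1, FALSE)
        inside <- (abs(x) >= band$inner_deg && abs(x) <= band$outer_deg &&
                   abs(y) >= band$inner_deg && abs(y) <= band$outer_deg)
        if (!inside) { x0[i] <- x; y0[i] <- y; break }
      }
    }
    data.frame(
      vertex_id = sprintf("%s_v%03d", areas[a], seq_len(n_per_area)),
      area = areas[a],
      x0 = x0, y0 = y0,
      sigma = stats::runif(n_per_area, sigma_range[1], sigma_range[2]) +
        area_sigma_shift[[a]],
      beta = 1, baseline = 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate multi-run vertex time series
#'
#' Runs the pRF forward model generatively: per vertex, condition and
#' run, the noiseless prediction is scaled by condition gain x area gain
#' x the vertex amplitude, then linear drift and AR(1) noise are added.
#' Per-area gains emulate the signal-to-noise gradient across the visual
#' hierarchy (V1 < V2 < V3); condition gains emulate the much stronger
#' response to the high-contrast mapping stimulus than to the
#' low-contrast and illusory bars.
#'
#' @param truth Ground-truth table from [sample_ground_truth()].
#' @param scaffold A [prf_scaffold()].
#' @param noise A [noise_model()].
#' @param condition_gains Named amplitude multipliers per condition.
#' @param area_gains Named amplitude multipliers per area.
#' @param n_runs Runs per condition.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_dataset"`: `ground_truth`
#'   (with per-condition SNR columns appended), `series` (condition ->
#'   run -> vertex x volume matrix), `design`, `seed`, gains and noise.
#' @export
simulate_runs <- function(truth, scaffold, noise = noise_model(),
                          condition_gains = c(mapping = 1.0, luminance = 0.25,
                                              kanizsa = 0.25, occlusion = 0.20),
                          area_gains = c(V1 = 0.7, V2 = 1.0, V3 = 1.3),
                          n_runs = 4, seed = 1) {
  stopifnot(inherits(scaffold, "prf_scaffold"), is.data.frame(truth))
  if (n_runs < 1) stop("n_runs must be at least 1", call. = FALSE)
  n_vert <- nrow(truth)
  n <- scaffold$n
  set.seed(.stream_seed(seed, "runs"))

  preds <- matrix(0, n_vert, n)
  for (v in seq_len(n_vert))
    preds[v, ] <- .predict_unit(scaffold, truth$x0[v], truth$y0[v],
                                truth$sigma[v])
  pred_sd <- apply(preds, 1, stats::sd)
  ag <- area_gains[truth$area]

  series <- list()
  for (cond in names(condition_gains)) {
    amp <- truth$beta * condition_gains[[cond]] * ag
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      m <- matrix(0, n_vert, n)
      for (v in seq_len(n_vert))
        m[v, ] <- amp[v] * preds[v, ] + truth$baseline[v] +
          .drift_and_noise(n, noise)
      rownames(m) <- truth$vertex_id
      runs[[r]] <- m
    }
    series[[cond]] <- runs
    truth[[paste0("snr_", cond)]] <-
      if (noise$white_sd > 0) amp * pred_sd / noise$white_sd else Inf
  }
  structure(list(ground_truth = truth, series = series,
                 design = scaffold$design, seed = seed,
                 condition_gains = condition_gains, area_gains = area_gains,
                 noise = noise, n_runs = n_runs),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic pRF dataset: %d vertices, %d conditions x %d runs x %d volumes (seed %d)\n",
              nrow(x$ground_truth), length(x$series), x$n_runs,
              x$design$n_volumes_retained, x$seed))
  invisible(x)
}

#' Simulate a fixation gaze trace
#'
#' Centred Gaussian fixation jitter sampled at the eye-tracker rate,
#' mimicking a compliant observer holding fixation for a run.
#'
#' @param duration_s Trace duration (s); 225 s covers one run with
#'   tracker lead-in.
#' @param rate_hz Sampling rate (Hz).
#' @param sd_deg Jitter standard deviation per axis (degrees).
#' @param seed Integer seed.
#' @return Data frame with time_s, x_deg, y_deg.
#' @export
simulate_gaze <- function(duration_s = 225, rate_hz = 60, sd_deg = 0.3,
                          seed = 1) {
  if (duration_s <= 0 || rate_hz <= 0 || sd_deg < 0)
    stop("duration, rate must be positive and sd non-negative", call. = FALSE)
  set.seed(.stream_seed(seed, "gaze"))
  n <- as.integer(round(duration_s * rate_hz))
  data.frame(time_s = (seq_len(n) - 1) / rate_hz,
             x_deg = stats::rnorm(n, 0, sd_deg),
             y_deg = stats::rnorm(n, 0, sd_deg))
}
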