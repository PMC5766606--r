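#' pRF parameter set
#'
#' A population receptive field is a 2-D isotropic Gaussian in the visual
#' field with centre `(x0, y0)` and size `sigma`, scaled by a response
#' amplitude `beta` on top of a `baseline` (both in normalized BOLD
#' units).
#'
#' @param x0,y0 Centre in degrees of visual angle.
#' @param sigma Gaussian standard deviation in degrees (> 0).
#' @param beta Response amplitude.
#' @param baseline Additive baseline.
#' @return An object of class `"prf_params"`.
#' @export
prf_params <- function(x0 = 0, y0 = 0, sigma = 1, beta = 1, baseline = 0) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive finite number", call. = FALSE)
  if (!all(is.finite(c(x0, y0, beta, baseline))))
    stop("pRF parameters must be finite", call. = FALSE)
  structure(list(x0 = x0, y0 = y0, sigma = sigma,
                 beta = beta, baseline = baseline),
            class = "prf_params")
}

#' Gaussian receptive-field profile on a grid
#'
#' Evaluates `exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))` at every cell
#' centre.  No normalization constant is applied; absolute scale is
#' absorbed into the amplitude parameter.
#'
#' @param params A [prf_params()] (only the position fields are used).
#' @param grid A [visual_field_grid()].
#' @return A `grid$nx` x `grid$ny` matrix, rows indexing x, columns y.
#' @export
gaussian_field <- function(params, grid = visual_field_grid()) {
  stopifnot(inherits(grid, "visual_field_grid"))
  if (!is.finite(params$sigma) || params$sigma <= 0)
    stop("sigma must be a positive finite number", call. = FALSE)
  gx <- exp(-(grid$xs - params$x0)^2 / (2 * params$sigma^2))
  gy <- exp(-(grid$ys - params$y0)^2 / (2 * params$sigma^2))
  outer(gx, gy)
}

#' Per-volume overlap of an aperture movie with a receptive field
#'
#' For each retained volume, sums the field over the cells the stimulus
#' occupies and multiplies by the cell area: the neural drive to the pRF.
#'
#' @param movie A [build_aperture_movie()] result.
#' @param field A field matrix from [gaussian_field()] on the same grid.
#' @return Numeric vector, one value per retained volume.
#' @export
neural_overlap <- function(movie, field) {
  stopifnot(inherits(movie, "aperture_movie"))
  if (length(field) != nrow(movie$frames))
    stop("field and movie grids do not match", call. = FALSE)
  as.vector(crossprod(movie$frames, as.vector(field))) * movie$grid$cell_area
}

# Fast path: identical to neural_overlap(movie, gaussian_field(...)) for
# bar-rectangle frames, using the separability of the Gaussian over the
# rectangular cell block (exact, not an approximation).
.overlap_fast <- function(movie, x0, y0, sigma) {
  g <- movie$grid
  s2 <- 2 * sigma^2
  csx <- c(0, cumsum(exp(-(g$xs - x0)^2 / s2)))
  csy <- c(0, cumsum(exp(-(g$ys - y0)^2 / s2)))
  xr <- movie$x_range
  yr <- movie$y_range
  out <- numeric(nrow(xr))
  on <- !is.na(xr[, 1]) & !is.na(yr[, 1])
  out[on] <- (csx[xr[on, 2] + 1L] - csx[xr[on, 1]]) *
    (csy[yr[on, 2] + 1L] - csy[yr[on, 1]]) * g$cell_area
  out
}

#' Precomputed forward-model scaffold
#'
#' Bundles the aperture movie, run design and HRF together with the
#' precomputed convolution map and detrending projection so that
#' per-candidate predictions reduce to one matrix product.  All fitting
#' and simulation functions accept a scaffold.
#'
#' @param movie A [build_aperture_movie()] result.
#' @param hrf An [hrf_spec()].
#' @return An object of class `"prf_scaffold"`.
#' @export
prf_scaffold <- function(movie = build_aperture_movie(), hrf = hrf_spec()) {
  design <- movie$design
  W <- .conv_matrix(design, hrf)
  retained <- (design$n_volumes_dummy + 1L):design$n_volumes_total
  n <- design$n_volumes_retained
  # orthonormal-ish basis for intercept + linear trend, for detrending
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  H <- X %*% solve(crossprod(X), t(X))   # hat matrix of the trend fit
  structure(list(movie = movie, design = design, hrf = hrf,
                 W_retained = W[, retained, drop = FALSE],
                 trend_hat = H, n = n),
            class = "prf_scaffold")
}

# remove intercept + linear trend (the same projection preprocessing
# applies to the data); accepts a vector or a column-wise matrix
.detrend <- function(scaffold, v) {
  out <- v - scaffold$trend_hat %*% v
  if (is.null(dim(v))) as.vector(out) else out
}

# unit-amplitude, zero-baseline BOLD prediction for a candidate position
.predict_unit <- function(scaffold, x0, y0, sigma) {
  drive <- .overlap_fast(scaffold$movie, x0, y0, sigma)
  as.vector(scaffold$W_retained %*% drive)
}

#' Predicted BOLD time series for a pRF
#'
#' Overlap of the aperture with the Gaussian pRF per volume, convolved
#' with the haemodynamic kernel at `dt` resolution (with the blank dummy
#' period as convolution history), sampled at the retained volume onsets,
#' scaled by `beta` and shifted by `baseline`.
#'
#' @param params A [prf_params()].
#' @param scaffold A [prf_scaffold()].
#' @return Numeric vector, one value per retained volume.
#' @export
predict_timeseries <- function(params, scaffold) {
  stopifnot(inherits(scaffold, "prf_scaffold"))
  if (!is.finite(params$sigma) || params$sigma <= 0)
    stop("sigma must be a positive finite number", call. = FALSE)
  params$beta * .predict_unit(scaffold, params$x0, params$y0, params$sigma) +
    params$baseline
}
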