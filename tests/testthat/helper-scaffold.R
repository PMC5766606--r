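# Shared fixtures, built once per test run (the default scaffold and
# coarse bank are used by many files and take ~2 s to construct).
.fixtures <- new.env(parent = emptyenv())

default_scaffold <- function() {
  if (is.null(.fixtures$scaf))
    .fixtures$scaf <- prf_scaffold(build_aperture_movie())
  .fixtures$scaf
}

default_bank <- function() {
  if (is.null(.fixtures$bank))
    .fixtures$bank <- prediction_bank(default_scaffold())
  .fixtures$bank
}

# Closed-form overlap of an axis-aligned rectangle with an un-normalized
# isotropic Gaussian: 2 pi sigma^2 * dPhi_x * dPhi_y.  Independent oracle
# for the raster sums.
rect_overlap_closed_form <- function(rect, x0, y0, sigma) {
  2 * pi * sigma^2 *
    (pnorm((rect[["x_max"]] - x0) / sigma) - pnorm((rect[["x_min"]] - x0) / sigma)) *
    (pnorm((rect[["y_max"]] - y0) / sigma) - pnorm((rect[["y_min"]] - y0) / sigma))
}

# Build an aperture-movie object from an explicit list of rectangles
# (NULL entries = blank frames), mirroring the package's centre-sampling
# rasterization; used for shift/monotonicity property tests.
movie_from_rects <- function(rects, grid = visual_field_grid()) {
  n_frames <- length(rects)
  xr <- yr <- matrix(NA_integer_, n_frames, 2)
  frames <- matrix(FALSE, grid$nx * grid$ny, n_frames)
  for (k in seq_len(n_frames)) {
    r <- rects[[k]]
    if (is.null(r)) next
    xi <- which(grid$xs >= r[["x_min"]] - 1e-9 & grid$xs <= r[["x_max"]] + 1e-9)
    yi <- which(grid$ys >= r[["y_min"]] - 1e-9 & grid$ys <= r[["y_max"]] + 1e-9)
    if (!length(xi) || !length(yi)) next
    xr[k, ] <- range(xi); yr[k, ] <- range(yi)
    cells <- as.vector(outer(xr[k, 1]:xr[k, 2],
                             (yr[k, 1]:yr[k, 2] - 1L) * grid$nx, `+`))
    frames[cells, k] <- TRUE
  }
  structure(list(frames = frames, rects = rects, x_range = xr, y_range = yr,
                 frame_times_s = seq_len(n_frames) - 1, grid = grid,
                 design = NULL),
            class = "aperture_movie")
}
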