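#' Display geometry of the stimulation setup
#'
#' Describes the projection screen and viewing distance used to convert
#' between pixels and degrees of visual angle.
#'
#' @param screen_width_cm,screen_height_cm Physical screen size in cm.
#' @param res_x_px,res_y_px Screen resolution in pixels.
#' @param view_dist_cm Eye-to-screen distance in cm.
#'
#' @return An object of class `"display_geometry"`.
#' @examples
#' geom <- display_geometry()
#' px_to_deg(428, geom)   # side of the central grey occluder, ~6.7 deg
#' @export
display_geometry <- function(screen_width_cm = 36.8, screen_height_cm = 20.2,
                             res_x_px = 1920L, res_y_px = 1080L,
                             view_dist_cm = 68) {
  vals <- c(screen_width_cm, screen_height_cm, res_x_px, res_y_px, view_dist_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid display geometry: all fields must be strictly positive",
         call. = FALSE)
  structure(list(screen_width_cm = screen_width_cm,
                 screen_height_cm = screen_height_cm,
                 res_x_px = as.integer(res_x_px),
                 res_y_px = as.integer(res_y_px),
                 view_dist_cm = view_dist_cm),
            class = "display_geometry")
}

#' Convert a pixel extent to degrees of visual angle
#'
#' Uses the full tangent formula `2 * atan(s / (2 d))` where `s` is the
#' physical extent of the pixels on screen and `d` the viewing distance.
#' The vertical pixel pitch (screen height / vertical resolution) is used:
#' with the default geometry this reproduces the printed stimulus sizes
#' (occluder 6.7 deg, brick 11.4 deg, fixation dot 0.08 deg, screen height
#' 16.9 deg).
#'
#' @param pixels Extent in pixels (non-negative; vectorized).
#' @param geom A [display_geometry()].
#' @return Visual angle in degrees.
#' @export
px_to_deg <- function(pixels, geom = display_geometry()) {
  stopifnot(inherits(geom, "display_geometry"))
  if (any(pixels < 0)) stop("pixels must be >= 0", call. = FALSE)
  size_cm <- pixels * geom$screen_height_cm / geom$res_y_px
  2 * atan(size_cm / (2 * geom$view_dist_cm)) * 180 / pi
}

#' Carpet and bar layout, in degrees of visual angle
#'
#' The "carpet" is the central grey square occluder over the brick
#' background; mapping bars traverse it.  The bar's long axis overlaps the
#' brick image beyond the occluder on either side.
#'
#' @param occluder_side_deg Side of the grey occluder square.
#' @param brick_side_deg Side of the brick background square.
#' @param bar_width_deg Bar width along its motion axis.
#' @param bar_overlap_deg Overlap of the bar with the brick beyond the
#'   occluder, per side; bar length = occluder + 2 * overlap.
#' @param plus_sign_halfwidth_deg Half-width of the exclusion zone around
#'   the cardinal axes (the jagged "plus sign"); used by the ROI band.
#'
#' @return An object of class `"carpet_spec"` with an additional computed
#'   field `bar_length_deg`.
#' @export
carpet_spec <- function(occluder_side_deg = 6.7, brick_side_deg = 11.4,
                        bar_width_deg = 0.9, bar_overlap_deg = 2.1,
                        plus_sign_halfwidth_deg = 0.75) {
  if (occluder_side_deg >= brick_side_deg)
    stop("occluder must be smaller than the brick background", call. = FALSE)
  stopifnot(bar_width_deg > 0, bar_overlap_deg >= 0)
  structure(list(occluder_side_deg = occluder_side_deg,
                 brick_side_deg = brick_side_deg,
                 bar_width_deg = bar_width_deg,
                 bar_overlap_deg = bar_overlap_deg,
                 plus_sign_halfwidth_deg = plus_sign_halfwidth_deg,
                 bar_length_deg = occluder_side_deg + 2 * bar_overlap_deg),
            class = "carpet_spec")
}

#' Run design of one bar-mapping scan
#'
#' One run is a 10 s initial blank (dummy volumes, discarded) followed by
#' six 30 s trials: four bar sweeps in the order Right, Up, Left, Down,
#' with a null (blank) trial after the second and after the fourth sweep.
#' Each sweep moves the bar in 30 equal 1 s steps.
#'
#' @param trial_dur_s Trial duration in seconds.
#' @param step_dur_s Duration of one bar step.
#' @param steps_per_sweep Number of bar steps in one sweep.
#' @param dummy_dur_s Initial blank period whose volumes are discarded.
#' @param tr_s Repetition time (one volume) in seconds.
#'
#' @return An object of class `"run_design"` with the trial sequence and
#'   volume bookkeeping (`n_volumes_total`, `n_volumes_retained`).
#' @export
run_design <- function(trial_dur_s = 30, step_dur_s = 1, steps_per_sweep = 30,
                       dummy_dur_s = 10, tr_s = 1) {
  vals <- c(trial_dur_s, step_dur_s, steps_per_sweep, dummy_dur_s, tr_s)
  if (any(!is.finite(vals)) || any(vals[-4] <= 0) || dummy_dur_s < 0)
    stop("invalid run design timing", call. = FALSE)
  sequence <- c("bar_right", "bar_up", "null", "bar_left", "bar_down", "null")
  n_total <- as.integer(round((dummy_dur_s + length(sequence) * trial_dur_s) / tr_s))
  n_dummy <- as.integer(round(dummy_dur_s / tr_s))
  structure(list(trial_sequence = sequence,
                 trial_dur_s = trial_dur_s,
                 step_dur_s = step_dur_s,
                 steps_per_sweep = as.integer(steps_per_sweep),
                 dummy_dur_s = dummy_dur_s,
                 tr_s = tr_s,
                 n_volumes_dummy = n_dummy,
                 n_volumes_total = n_total,
                 n_volumes_retained = n_total - n_dummy),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("Bar-mapping run design\n")
  cat("  trials:", paste(x$trial_sequence, collapse = ", "), "\n")
  cat(sprintf("  trial %gs, %d steps of %gs, dummy %gs, TR %gs\n",
              x$trial_dur_s, x$steps_per_sweep, x$step_dur_s,
              x$dummy_dur_s, x$tr_s))
  cat(sprintf("  volumes: %d total, %d retained\n",
              x$n_volumes_total, x$n_volumes_retained))
  invisible(x)
}

#' Raster support for stimulus apertures and pRF profiles
#'
#' A square grid of cells covering the visual field, symmetric about
#' fixation.  Coordinates: x positive rightward, y positive upward, origin
#' at fixation.  Cells are centre-sampled: a cell belongs to a region iff
#' its centre does.
#'
#' @param extent_deg Half-extent; the grid covers `[-extent, extent]` in
#'   both x and y.  The default matches the maximal eccentricity of the
#'   standard mapping stimulus (8.5 deg).
#' @param cell_deg Cell side in degrees.
#'
#' @return An object of class `"visual_field_grid"` with cell-centre axes
#'   `xs`, `ys` and the cell area.
#' @export
visual_field_grid <- function(extent_deg = 8.5, cell_deg = 0.1) {
  stopifnot(extent_deg > 0, cell_deg > 0)
  n <- as.integer(round(2 * extent_deg / cell_deg))
  xs <- -extent_deg + (seq_len(n) - 0.5) * cell_deg
  structure(list(x_min_deg = -extent_deg, x_max_deg = extent_deg,
                 y_min_deg = -extent_deg, y_max_deg = extent_deg,
                 cell_deg = cell_deg, nx = n, ny = n,
                 xs = xs, ys = xs, cell_area = cell_deg^2),
            class = "visual_field_grid")
}

#' Bar rectangle for one sweep step
#'
#' The bar's long axis is perpendicular to its motion.  Bar centres
#' traverse the occluder width in `steps_per_sweep` equal steps, spanning
#' it symmetrically: the first centre sits half a step inside the occluder
#' edge, so step k of a leftward sweep mirrors step (n-1-k) of the
#' rightward sweep.
#'
#' @param direction One of `"bar_right"`, `"bar_up"`, `"bar_left"`,
#'   `"bar_down"` (direction of motion).
#' @param step_index 0-based step within the sweep.
#' @param carpet A [carpet_spec()].
#' @param steps_per_sweep Number of steps in the sweep.
#'
#' @return Named numeric vector `c(x_min, x_max, y_min, y_max)` in degrees.
#' @export
bar_rect <- function(direction, step_index, carpet = carpet_spec(),
                     steps_per_sweep = 30L) {
  direction <- match.arg(direction,
                         c("bar_right", "bar_up", "bar_left", "bar_down"))
  if (step_index < 0 || step_index >= steps_per_sweep)
    stop("step_index out of range [0, steps_per_sweep)", call. = FALSE)
  travel <- carpet$occluder_side_deg
  step <- travel / steps_per_sweep
  pos <- -travel / 2 + step / 2 + step_index * step  # centre along motion axis
  hw <- carpet$bar_width_deg / 2
  hl <- carpet$bar_length_deg / 2
  switch(direction,
    bar_right = c(x_min = pos - hw, x_max = pos + hw, y_min = -hl, y_max = hl),
    bar_left  = c(x_min = -pos - hw, x_max = -pos + hw, y_min = -hl, y_max = hl),
    bar_up    = c(x_min = -hl, x_max = hl, y_min = pos - hw, y_max = pos + hw),
    bar_down  = c(x_min = -hl, x_max = hl, y_min = -pos - hw, y_max = -pos + hw))
}

# Index range of grid-axis cells whose centres fall inside [lo, hi].
# A small tolerance keeps mirrored sweeps bit-identical at cell boundaries.
.axis_cells_inside <- function(axis, lo, hi, eps = 1e-9) {
  idx <- which(axis >= lo - eps & axis <= hi + eps)
  if (length(idx) == 0L) integer(0) else range(idx)
}

#' Binary aperture movie for one run
#'
#' Rasterizes the bar position of every retained volume into a binary mask
#' on a visual-field grid.  Frames during null trials are all-zero; dummy
#' volumes are not represented (the movie has one frame per *retained*
#' volume).  All three stimulus conditions share the same bar geometry, so
#' they share this movie: the conditions differ in how the bar is
#' rendered, not where it is.
#'
#' @param design A [run_design()].
#' @param carpet A [carpet_spec()].
#' @param grid A [visual_field_grid()]; must cover the union of bar
#'   positions.
#'
#' @return An object of class `"aperture_movie"`: `frames` is an
#'   (n cells) x (n frames) logical matrix (cells in column-major grid
#'   order, x fastest), `rects` the per-frame bar rectangle (or NULL for
#'   blank frames), `frame_times_s` volume onsets relative to run start.
#' @export
build_aperture_movie <- function(design = run_design(), carpet = carpet_spec(),
                                 grid = visual_field_grid()) {
  half_span <- max(carpet$bar_length_deg / 2, carpet$occluder_side_deg / 2)
  if (grid$x_max_deg < half_span || grid$y_max_deg < half_span)
    stop("grid does not cover the bar sweep region", call. = FALSE)

  vols_per_trial <- as.integer(round(design$trial_dur_s / design$tr_s))
  n_frames <- design$n_volumes_retained
  rects <- vector("list", n_frames)
  xr <- yr <- matrix(NA_integer_, nrow = n_frames, ncol = 2)

  f <- 0L
  for (trial in design$trial_sequence) {
    for (v in seq_len(vols_per_trial)) {
      f <- f + 1L
      if (trial == "null") next
      step <- ((v - 1L) * design$tr_s) %/% design$step_dur_s
      if (step >= design$steps_per_sweep) next  # trial longer than the sweep
      r <- bar_rect(trial, step, carpet, design$steps_per_sweep)
      rects[[f]] <- r
      xi <- .axis_cells_inside(grid$xs, r[["x_min"]], r[["x_max"]])
      yi <- .axis_cells_inside(grid$ys, r[["y_min"]], r[["y_max"]])
      if (length(xi)) xr[f, ] <- xi
      if (length(yi)) yr[f, ] <- yi
    }
  }
  stopifnot(f == n_frames)

  frames <- matrix(FALSE, nrow = grid$nx * grid$ny, ncol = n_frames)
  for (k in seq_len(n_frames)) {
    if (is.na(xr[k, 1]) || is.na(yr[k, 1])) next
    cols <- xr[k, 1]:xr[k, 2]
    rows <- yr[k, 1]:yr[k, 2]
    cells <- as.vector(outer(cols, (rows - 1L) * grid$nx, `+`))
    frames[cells, k] <- TRUE
  }

  structure(list(frames = frames,
                 rects = rects,
                 x_range = xr, y_range = yr,
                 frame_times_s = design$dummy_dur_s +
                   (seq_len(n_frames) - 1) * design$tr_s,
                 grid = grid, design = design),
            class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("Aperture movie: %d frames on a %dx%d grid (%.2g deg cells), %d blank\n",
              ncol(x$frames), x$grid$nx, x$grid$ny, x$grid$cell_deg,
              sum(vapply(x$rects, is.null, logical(1)))))
  invisible(x)
}
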