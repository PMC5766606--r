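#' Preprocess the runs of one vertex
#'
#' Per run: remove a least-squares linear trend over volumes, z-score
#' (mean 0, sd 1), then average across runs elementwise.  A run whose
#' detrended signal has zero variance contributes an all-zero series and
#' is flagged.
#'
#' @param runs Numeric matrix, runs in rows, retained volumes in columns
#'   (a single run may be given as a vector).
#' @return Numeric vector of the averaged preprocessed series, with
#'   attributes `zero_variance` (logical per run) and `ok` (FALSE when
#'   every run was flat).
#' @export
preprocess_runs <- function(runs) {
  if (is.null(dim(runs))) runs <- matrix(runs, nrow = 1)
  if (nrow(runs) < 1L) stop("at least one run is required", call. = FALSE)
  n <- ncol(runs)
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  hat <- X %*% solve(crossprod(X), t(X))
  flat <- logical(nrow(runs))
  pp <- matrix(0, nrow(runs), n)
  for (r in seq_len(nrow(runs))) {
    d <- runs[r, ] - as.vector(hat %*% runs[r, ])
    s <- stats::sd(d)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      flat[r] <- TRUE
      next
    }
    pp[r, ] <- d / s
  }
  if (any(flat))
    warning(sum(flat), " zero-variance run(s) set to zero", call. = FALSE)
  out <- colMeans(pp)
  attr(out, "zero_variance") <- flat
  attr(out, "ok") <- !all(flat)
  out
}

#' Coarse-stage search grid
#'
#' Candidate pRF centres on a square lattice and log-spaced candidate
#' sizes.  Defaults span the carpet region with margin at a tractable
#' bank size.
#'
#' @param x0,y0 Candidate centre coordinates (degrees).
#' @param sigma Candidate sizes (degrees, log-spaced, > 0).
#' @return An object of class `"search_grid"`.
#' @export
search_grid <- function(x0 = seq(-4, 4, by = 0.25),
                        y0 = seq(-4, 4, by = 0.25),
                        sigma = c(0.2, 0.3, 0.45, 0.67, 1.0, 1.5, 2.25)) {
  if (!length(x0) || !length(y0) || !length(sigma))
    stop("empty search grid", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma candidates must be positive", call. = FALSE)
  structure(list(x0 = x0, y0 = y0, sigma = sigma), class = "search_grid")
}

#' Precomputed bank of coarse-stage predictions
#'
#' Builds the unit-amplitude BOLD prediction for every point of the
#' search grid, detrended and standardized so that the coarse stage is a
#' single correlation sweep.  Candidates are ordered lexicographically by
#' (x0, y0, sigma); correlation ties resolve to the first candidate in
#' that order.
#'
#' @param scaffold A [prf_scaffold()].
#' @param search A [search_grid()].
#' @return An object of class `"prediction_bank"` with the candidate
#'   table and the standardized prediction matrix.
#' @export
prediction_bank <- function(scaffold, search = search_grid()) {
  stopifnot(inherits(scaffold, "prf_scaffold"), inherits(search, "search_grid"))
  movie <- scaffold$movie
  g <- movie$grid
  xr <- movie$x_range
  yr <- movie$y_range
  on <- !is.na(xr[, 1]) & !is.na(yr[, 1])
  n_frames <- nrow(xr)

  params <- expand.grid(sigma = search$sigma, y0 = search$y0, x0 = search$x0,
                        KEEP.OUT.ATTRS = FALSE)[, c("x0", "y0", "sigma")]
  n_cand <- nrow(params)
  preds <- matrix(0, nrow = scaffold$n, ncol = n_cand)

  col <- function(cs, rng) cs[rng[, 2] + 1L] - cs[rng[, 1]]
  k <- 0L
  for (x0 in search$x0) {
    for (y0 in search$y0) {
      for (s in search$sigma) {
        k <- k + 1L
        s2 <- 2 * s^2
        csx <- c(0, cumsum(exp(-(g$xs - x0)^2 / s2)))
        csy <- c(0, cumsum(exp(-(g$ys - y0)^2 / s2)))
        drive <- numeric(n_frames)
        drive[on] <- (csx[xr[on, 2] + 1L] - csx[xr[on, 1]]) *
          (csy[yr[on, 2] + 1L] - csy[yr[on, 1]]) * g$cell_area
        preds[, k] <- scaffold$W_retained %*% drive
      }
    }
  }
  preds <- .detrend(scaffold, preds)
  mu <- colMeans(preds)
  preds <- sweep(preds, 2, mu)
  nrm <- sqrt(colSums(preds^2))
  degenerate <- nrm < .Machine$double.eps^0.5
  nrm[degenerate] <- 1
  preds <- sweep(preds, 2, nrm, "/")
  preds[, degenerate] <- 0
  structure(list(params = params, preds = preds, search = search,
                 degenerate = degenerate),
            class = "prediction_bank")
}

#' Coarse grid-search stage
#'
#' Finds the search-grid candidate whose unit-amplitude prediction has
#' the highest Pearson correlation with the preprocessed series.
#'
#' @param averaged Preprocessed averaged series ([preprocess_runs()]).
#' @param bank A [prediction_bank()].
#' @return List with the winning `x0`, `y0`, `sigma` and the correlation
#'   `r`.
#' @export
coarse_fit <- function(averaged, bank) {
  if (!inherits(bank, "prediction_bank") || ncol(bank$preds) == 0L)
    stop("prediction bank is empty", call. = FALSE)
  v <- as.vector(averaged) - mean(averaged)
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5)
    stop("averaged series has zero variance", call. = FALSE)
  r <- as.vector(crossprod(bank$preds, v / nv))
  best <- which.max(r)
  list(x0 = bank$params$x0[best], y0 = bank$params$y0[best],
       sigma = bank$params$sigma[best], r = r[best], index = best)
}

#' Fine optimization stage
#'
#' Refines the coarse estimate by a derivative-free Nelder-Mead simplex
#' over (x0, y0, log sigma), maximizing the squared Pearson correlation
#' between the (detrended) model prediction and the preprocessed series.
#' Amplitude and baseline are solved by ordinary least squares at the
#' optimum.  If the simplex fails to improve on the coarse candidate, the
#' coarse parameters are returned with `converged = FALSE`.
#'
#' @param averaged Preprocessed averaged series.
#' @param init Coarse-stage result ([coarse_fit()]).
#' @param scaffold A [prf_scaffold()].
#' @param maxit Maximum function evaluations.
#' @param reltol Relative convergence tolerance on the objective.
#' @return List with fields `params` ([prf_params()]), `r_squared`,
#'   `polar_rad`, `ecc_deg`, `converged`, `neg_beta`.
#' @export
fine_fit <- function(averaged, init, scaffold, maxit = 400, reltol = 1e-6) {
  y <- as.vector(averaged)
  y <- y - mean(y)
  ny2 <- sum(y^2)
  if (ny2 < .Machine$double.eps^0.5) {
    pe <- derive_polar_ecc(init$x0, init$y0)
    return(list(params = prf_params(init$x0, init$y0, init$sigma, 0, 0),
                r_squared = 0, polar_rad = pe[1, "polar_rad"],
                ecc_deg = pe[1, "ecc_deg"], converged = FALSE,
                neg_beta = FALSE))
  }

  unit_pred <- function(par) {
    p <- .detrend(scaffold, .predict_unit(scaffold, par[1], par[2], exp(par[3])))
    p - mean(p)
  }
  obj <- function(par) {
    p <- unit_pred(par)
    np2 <- sum(p^2)
    if (np2 < .Machine$double.eps) return(0)
    -(sum(p * y)^2 / (np2 * ny2))
  }
  start <- c(init$x0, init$y0, log(init$sigma))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  r2_fine <- -opt$value
  r2_coarse <- init$r^2

  if (r2_fine >= r2_coarse) {
    par <- opt$par
    r2 <- r2_fine
    converged <- opt$convergence == 0
  } else {
    par <- start
    r2 <- r2_coarse
    converged <- FALSE
  }
  p <- unit_pred(par)
  np2 <- sum(p^2)
  beta <- if (np2 > 0) sum(p * y) / np2 else 0
  baseline <- mean(averaged)  # regressor is centred, so OLS intercept = data mean
  pe <- derive_polar_ecc(par[1], par[2])
  list(params = prf_params(par[1], par[2], exp(par[3]), beta, baseline),
       r_squared = r2, polar_rad = pe[1, "polar_rad"], ecc_deg = pe[1, "ecc_deg"],
       converged = converged, neg_beta = beta < 0)
}

#' Polar angle and eccentricity of a pRF centre
#'
#' Polar angle is measured from the right horizontal meridian,
#' counter-clockwise positive, in radians; eccentricity is the distance
#' from fixation in degrees.  The origin maps to polar angle 0 by
#' convention.
#'
#' @param x0,y0 Centre coordinates in degrees (vectorized).
#' @return A two-column matrix with `polar_rad` and `ecc_deg`.
#' @export
derive_polar_ecc <- function(x0, y0) {
  polar <- atan2(y0, x0)
  polar[x0 == 0 & y0 == 0] <- 0
  cbind(polar_rad = polar, ecc_deg = sqrt(x0^2 + y0^2))
}

#' Fit a population receptive field to one vertex
#'
#' The package's central estimator: preprocesses the runs of one vertex
#' (linear detrend, z-score, average), finds the best coarse search-grid
#' candidate by correlation, and refines it with a Nelder-Mead simplex
#' maximizing goodness of fit.
#'
#' @param runs Numeric matrix of raw signal, runs x retained volumes (one
#'   run may be a vector).
#' @param scaffold A [prf_scaffold()] describing stimulus, design and
#'   HRF.
#' @param bank A [prediction_bank()]; built from `search` if omitted.
#' @param search A [search_grid()] (used only when `bank` is missing).
#' @param maxit,reltol Fine-stage control, see [fine_fit()].
#' @return An object of class `"prf_fit"` with the estimated
#'   [prf_params()], `r_squared`, `polar_rad`, `ecc_deg`, `converged`,
#'   the preprocessed data and the fitted series.
#' @examples
#' \donttest{
#' scaf <- prf_scaffold(build_aperture_movie())
#' truth <- prf_params(x0 = 1.5, y0 = -2, sigma = 0.8, beta = 1)
#' y <- predict_timeseries(truth, scaf)
#' fit <- prf_fit(y, scaf)
#' coef(fit)
#' }
#' @export
prf_fit <- function(runs, scaffold, bank = NULL, search = search_grid(),
                    maxit = 400, reltol = 1e-6) {
  stopifnot(inherits(scaffold, "prf_scaffold"))
  if (is.null(bank)) bank <- prediction_bank(scaffold, search)
  averaged <- preprocess_runs(runs)
  if (!attr(averaged, "ok")) {
    res <- list(params = prf_params(0, 0, bank$params$sigma[1], 0, 0),
                r_squared = 0, polar_rad = 0, ecc_deg = 0,
                converged = FALSE, neg_beta = FALSE, flat = TRUE)
    coarse <- NULL
  } else {
    coarse <- coarse_fit(averaged, bank)
    res <- fine_fit(averaged, coarse, scaffold, maxit = maxit, reltol = reltol)
    res$flat <- FALSE
  }
  fitted <- if (res$flat) rep(0, scaffold$n) else {
    p <- .detrend(scaffold,
                  .predict_unit(scaffold, res$params$x0, res$params$y0,
                                res$params$sigma))
    res$params$beta * (p - mean(p)) + mean(averaged)
  }
  structure(c(res, list(coarse = coarse, data = as.vector(averaged),
                        fitted_values = fitted, scaffold_n = scaffold$n)),
            class = "prf_fit")
}

#' Fit pRFs to every vertex of a dataset
#'
#' Orchestrates preprocess, coarse and fine stages per vertex and
#' condition over a synthetic (or user-assembled) dataset, returning one
#' tidy row per vertex x condition.  Deterministic given its inputs.
#'
#' @param dataset A [simulate_runs()] result, or any list with elements
#'   `ground_truth` (data frame with `vertex_id`, `area`) and `series`
#'   (condition -> run -> vertex x volume matrix).
#' @param scaffold A [prf_scaffold()].
#' @param bank Optional precomputed [prediction_bank()].
#' @param search A [search_grid()] (used only when `bank` is missing).
#' @param conditions Conditions to fit (default: all in the dataset).
#' @param maxit,reltol Fine-stage control, see [fine_fit()].
#' @return Data frame with columns vertex_id, area, condition, x0, y0,
#'   sigma, beta, baseline, r_squared, polar_rad, ecc_deg, converged.
#' @export
fit_prf_dataset <- function(dataset, scaffold, bank = NULL,
                            search = search_grid(), conditions = NULL,
                            maxit = 400, reltol = 1e-6) {
  stopifnot(is.list(dataset$series), is.data.frame(dataset$ground_truth))
  if (is.null(bank)) bank <- prediction_bank(scaffold, search)
  if (is.null(conditions)) conditions <- names(dataset$series)
  truth <- dataset$ground_truth
  n_vert <- nrow(truth)
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    runs <- dataset$series[[cond]]
    if (is.null(runs))
      stop("condition not present in dataset: ", cond, call. = FALSE)
    if (any(vapply(runs, ncol, 1L) != scaffold$n) ||
        any(vapply(runs, nrow, 1L) != n_vert))
      stop("dataset series do not match the design/ground truth", call. = FALSE)
    empty <- data.frame(
      vertex_id = character(0), area = character(0), condition = character(0),
      x0 = numeric(0), y0 = numeric(0), sigma = numeric(0), beta = numeric(0),
      baseline = numeric(0), r_squared = numeric(0), polar_rad = numeric(0),
      ecc_deg = numeric(0), converged = logical(0), stringsAsFactors = FALSE)
    rows <- vector("list", n_vert)
    for (v in seq_len(n_vert)) {
      vr <- do.call(rbind, lapply(runs, function(m) m[v, ]))
      f <- prf_fit(vr, scaffold, bank = bank, maxit = maxit, reltol = reltol)
      rows[[v]] <- data.frame(
        vertex_id = truth$vertex_id[v], area = truth$area[v],
        condition = cond,
        x0 = f$params$x0, y0 = f$params$y0, sigma = f$params$sigma,
        beta = f$params$beta, baseline = f$params$baseline,
        r_squared = f$r_squared, polar_rad = f$polar_rad,
        ecc_deg = f$ecc_deg, converged = f$converged,
        stringsAsFactors = FALSE)
    }
    out[[ci]] <- if (n_vert == 0L) empty else do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
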