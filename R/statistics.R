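#' Quadrant analysis band around the cardinal axes
#'
#' The analysis is restricted to pRF centres between `inner_deg` and
#' `outer_deg` from *both* cardinal axes: four rectangular quadrant
#' regions covering the carpet interior while excluding the fixation
#' "plus sign" zone and the carpet edges.
#'
#' @param inner_deg Minimum distance from either cardinal axis.
#' @param outer_deg Maximum distance from either cardinal axis.
#' @return An object of class `"roi_band"`.
#' @export
roi_band <- function(inner_deg = 0.75, outer_deg = 3.0) {
  if (!(inner_deg > 0 && inner_deg < outer_deg))
    stop("need 0 < inner_deg < outer_deg", call. = FALSE)
  structure(list(inner_deg = inner_deg, outer_deg = outer_deg),
            class = "roi_band")
}

#' Select pRFs inside the quadrant analysis band
#'
#' Keeps a vertex iff `inner <= |x0| <= outer` and `inner <= |y0| <=
#' outer` (bounds inclusive), with centres taken from the reference
#' (mapping) fit.
#'
#' @param fits Data frame with columns `x0` and `y0`.
#' @param band A [roi_band()].
#' @return Logical mask, one entry per row of `fits`.
#' @export
roi_filter <- function(fits, band = roi_band()) {
  if (!all(c("x0", "y0") %in% names(fits)))
    stop("fits must contain columns x0 and y0", call. = FALSE)
  ax <- abs(fits$x0); ay <- abs(fits$y0)
  ax >= band$inner_deg & ax <= band$outer_deg &
    ay >= band$inner_deg & ay <= band$outer_deg
}

#' Proportion of responsive vertices
#'
#' Fraction of selected vertices whose goodness of fit exceeds the
#' threshold (strictly; a vertex at exactly the threshold does not
#' count as responsive).
#'
#' @param fits Data frame with column `r_squared`.
#' @param mask Logical selection (default: all rows).
#' @param threshold R-squared cutoff.
#' @return A proportion in `[0, 1]`.
#' @export
responsive_fraction <- function(fits, mask = rep(TRUE, nrow(fits)),
                                threshold = 0.05) {
  r2 <- fits$r_squared[mask]
  if (length(r2) == 0L)
    stop("no vertices selected; proportion undefined", call. = FALSE)
  mean(r2 > threshold)
}

# Fisher z with clipping so r = +/-1 stays finite
.fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Correlate observed time courses with reference predictions
#'
#' For each vertex, Pearson correlation between its observed
#' (preprocessed) series and the forward prediction generated from that
#' vertex's reference (mapping-derived) pRF parameters; the summary is
#' the Fisher-z-converted average: `tanh(mean(atanh(r)))`.
#'
#' @param observed Matrix, vertex x volume, of preprocessed series.
#' @param reference_fits Data frame with `x0`, `y0`, `sigma`, one row
#'   per vertex, aligned with `observed`.
#' @param scaffold A [prf_scaffold()].
#' @return List with per-vertex `r`, the `zbar` (Fisher-z mean) and
#'   `summary` (its tanh back-transform), and `n_skipped` zero-variance
#'   vertices.
#' @export
prediction_correlation <- function(observed, reference_fits, scaffold) {
  stopifnot(nrow(observed) == nrow(reference_fits))
  preds <- .reference_predictions(reference_fits, scaffold)
  r <- .rowwise_cor(observed, preds)
  skipped <- !is.finite(r)
  z <- .fisher_z(r[!skipped])
  list(r = r, zbar = mean(z), summary = tanh(mean(z)),
       n_skipped = sum(skipped))
}

# detrended, centred unit predictions for a table of reference parameters
.reference_predictions <- function(reference_fits, scaffold) {
  n_vert <- nrow(reference_fits)
  preds <- matrix(0, n_vert, scaffold$n)
  for (v in seq_len(n_vert)) {
    p <- .detrend(scaffold,
                  .predict_unit(scaffold, reference_fits$x0[v],
                                reference_fits$y0[v], reference_fits$sigma[v]))
    preds[v, ] <- p
  }
  preds
}

# Pearson correlation of matched rows; NA for zero-variance rows
.rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a); b <- b - rowMeans(b)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  r <- rowSums(a * b) / (na * nb)
  r[na < .Machine$double.eps^0.5 | nb < .Machine$double.eps^0.5] <- NA_real_
  r
}

#' Vertex-shuffle permutation test of map coherence
#'
#' Tests whether observed-vs-predicted time-course correlations are
#' vertex-specific: the observed Fisher-z mean correlation is compared
#' with its distribution over random re-assignments of predictions to
#' vertices.  One-sided exceedance p with the add-one correction,
#' `p = (#\{null >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param observed Matrix, vertex x volume, of preprocessed series.
#' @param reference_fits Data frame with `x0`, `y0`, `sigma` per vertex.
#' @param scaffold A [prf_scaffold()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `"permutation_result"` with
#'   `observed_zbar`, `null_zbars`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(observed, reference_fits, scaffold,
                             n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  n_vert <- nrow(observed)
  if (n_vert < 2) stop("need at least 2 vertices", call. = FALSE)
  preds <- .reference_predictions(reference_fits, scaffold)

  oc <- observed - rowMeans(observed)
  pc <- preds - rowMeans(preds)
  on <- sqrt(rowSums(oc^2)); pn <- sqrt(rowSums(pc^2))
  keep <- on > .Machine$double.eps^0.5 & pn > .Machine$double.eps^0.5
  oc <- oc[keep, , drop = FALSE] / on[keep]
  pc <- pc[keep, , drop = FALSE] / pn[keep]
  nv <- nrow(oc)
  if (nv < 2) stop("fewer than 2 usable vertices", call. = FALSE)

  C <- .fisher_z(tcrossprod(oc, pc))   # C[i, j] = z(cor(obs_i, pred_j))
  observed_zbar <- mean(diag(C))
  set.seed(seed)
  null_zbars <- vapply(seq_len(n_perm), function(i) {
    mean(C[cbind(seq_len(nv), sample.int(nv))])
  }, numeric(1))
  p <- (sum(null_zbars >= observed_zbar) + 1) / (n_perm + 1)
  structure(list(observed_zbar = observed_zbar, null_zbars = null_zbars,
                 p_value = p, n_perm = n_perm, seed = seed,
                 n_vertices = nv, n_skipped = n_vert - nv),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Vertex-shuffle permutation test: zbar = %.4f, p = %.4g (%d permutations, %d vertices)\n",
              x$observed_zbar, x$p_value, x$n_perm, x$n_vertices))
  invisible(x)
}

#' Circular correlation of paired angles
#'
#' Fisher-Lee (1983) circular correlation in its pairwise form:
#' `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by the root
#' product of the marginal pairwise sums of squares.  Invariant to
#' rotating either vector and to jointly negating both, and -- unlike
#' the circular-mean-deviation variant -- well behaved when the angles
#' cluster in several modes (polar angles restricted to the four
#' quadrant ROIs have a near-zero resultant, which makes the circular
#' mean, and any statistic built on it, unstable).
#'
#' @param a,b Angle vectors in radians, equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when
#'   either vector has zero circular variance.
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need equal-length angle vectors of length >= 3", call. = FALSE)
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  num <- sum(sa * sb) / 2           # each unordered pair counted once
  den <- sqrt(sum(sa^2) * sum(sb^2)) / 2
  if (den < .Machine$double.eps^0.5) {
    warning("zero circular variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Between-condition consistency of pRF parameter maps
#'
#' For every visual area, parameter and unordered condition pair,
#' correlates the per-vertex parameter values of the two conditions
#' across the masked vertices: Spearman rank correlation for scalar
#' parameters, circular correlation for polar angle.
#'
#' @param fits Long data frame from [fit_prf_dataset()] (one row per
#'   vertex x condition).
#' @param mask Logical mask over *vertices* (aligned with the vertex set
#'   of one condition), typically from [roi_filter()] on the reference
#'   condition; default keeps all.
#' @param parameters Parameters to correlate; `polar` uses
#'   [circular_correlation()].
#' @return Data frame with area, parameter, cond_a, cond_b, method, n,
#'   r; cells with fewer than 3 usable vertices get `NA`.
#' @export
parameter_correlations <- function(fits, mask = NULL,
                                   parameters = c("polar", "ecc", "sigma",
                                                  "beta", "r_squared")) {
  cols <- c(polar = "polar_rad", ecc = "ecc_deg", sigma = "sigma",
            beta = "beta", r_squared = "r_squared")
  parameters <- match.arg(parameters, names(cols), several.ok = TRUE)
  conds <- unique(fits$condition)
  areas <- unique(fits$area)
  vertices <- unique(fits$vertex_id)
  if (is.null(mask)) mask <- rep(TRUE, length(vertices))
  keep_ids <- vertices[mask]

  out <- list(); k <- 0L
  for (area in areas) {
    sub <- fits[fits$area == area & fits$vertex_id %in% keep_ids, ]
    for (param in parameters) {
      col <- cols[[param]]
      wide <- stats::reshape(
        sub[, c("vertex_id", "condition", col)],
        idvar = "vertex_id", timevar = "condition", direction = "wide")
      for (i in seq_along(conds)) for (j in seq_len(i - 1L)) {
        va <- wide[[paste(col, conds[i], sep = ".")]]
        vb <- wide[[paste(col, conds[j], sep = ".")]]
        usable <- is.finite(va) & is.finite(vb)
        r <- if (sum(usable) >= 3) {
          if (param == "polar")
            suppressWarnings(circular_correlation(va[usable], vb[usable]))
          else
            stats::cor(va[usable], vb[usable], method = "spearman")
        } else NA_real_
        k <- k + 1L
        out[[k]] <- data.frame(area = area, parameter = param,
                               cond_a = conds[j], cond_b = conds[i],
                               method = if (param == "polar") "circular"
                                        else "spearman",
                               n = sum(usable), r = r,
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average correlations across subjects on the Fisher-z scale
#'
#' `tanh(mean(atanh(r)))` with clipping at `|r| = 1 - 1e-12`.
#'
#' @param r Vector of correlations (NAs dropped).
#' @return The back-transformed mean correlation.
#' @export
fisher_z_mean <- function(r) {
  r <- r[is.finite(r)]
  if (!length(r)) return(NA_real_)
  tanh(mean(.fisher_z(r)))
}

#' Gaze stability as median absolute deviation
#'
#' Median absolute deviation (no consistency scaling) of sampled gaze
#' positions along the horizontal and vertical dimensions.
#'
#' @param trace Data frame with `x_deg` and `y_deg` (from
#'   [simulate_gaze()] or an eye-tracker sample table).
#' @return Named vector `c(mad_x_deg, mad_y_deg)`.
#' @export
gaze_mad <- function(trace) {
  if (is.null(trace$x_deg) || is.null(trace$y_deg) || nrow(trace) < 1)
    stop("trace must contain x_deg/y_deg samples", call. = FALSE)
  c(mad_x_deg = stats::median(abs(trace$x_deg - stats::median(trace$x_deg))),
    mad_y_deg = stats::median(abs(trace$y_deg - stats::median(trace$y_deg))))
}
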