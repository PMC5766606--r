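#' @export
print.prf_fit <- function(x, ...) {
  cat("Population receptive field fit\n")
  cat(sprintf("  centre (%.3f, %.3f) deg, sigma %.3f deg\n",
              x$params$x0, x$params$y0, x$params$sigma))
  cat(sprintf("  beta %.3f, baseline %.3f, R^2 %.3f%s\n",
              x$params$beta, x$params$baseline, x$r_squared,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.prf_fit <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    polar_rad = object$polar_rad, ecc_deg = object$ecc_deg,
    r_squared = object$r_squared, converged = object$converged,
    neg_beta = object$neg_beta, flat = object$flat,
    coarse = object$coarse, n = object$scaffold_n)
  class(out) <- "summary.prf_fit"
  out
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat("Population receptive field fit\n\nParameters:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nPolar angle %.3f rad, eccentricity %.3f deg\n",
              x$polar_rad, x$ecc_deg))
  cat(sprintf("R^2 = %.4f over %d volumes; converged: %s\n",
              x$r_squared, x$n, x$converged))
  if (!is.null(x$coarse))
    cat(sprintf("Coarse stage: (%.2f, %.2f, %.2f) r = %.3f\n",
                x$coarse$x0, x$coarse$y0, x$coarse$sigma, x$coarse$r))
  if (x$neg_beta) cat("Note: negative response amplitude (flagged).\n")
  if (x$flat) cat("Note: all runs were flat; fit is degenerate.\n")
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) {
  p <- object$params
  c(x0 = p$x0, y0 = p$y0, sigma = p$sigma,
    beta = p$beta, baseline = p$baseline)
}

#' @export
fitted.prf_fit <- function(object, ...) object$fitted_values

#' @export
residuals.prf_fit <- function(object, ...) object$data - object$fitted_values

#' Predict from a fitted pRF
#'
#' Returns the model prediction for the fitted parameters (the fitted
#' series) or, given a scaffold, the forward-model prediction for new
#' parameters through [predict_timeseries()].
#'
#' @param object A [prf_fit()] result.
#' @param scaffold Optional [prf_scaffold()]; if supplied the raw
#'   (non-detrended) forward prediction is computed for `params`.
#' @param params Optional [prf_params()] overriding the fitted ones.
#' @param ... Unused.
#' @export
predict.prf_fit <- function(object, scaffold = NULL, params = NULL, ...) {
  if (is.null(scaffold)) return(object$fitted_values)
  if (is.null(params))
    params <- prf_params(object$params$x0, object$params$y0,
                         object$params$sigma, object$params$beta,
                         object$params$baseline)
  predict_timeseries(params, scaffold)
}

#' Plot a fitted pRF time course
#'
#' Observed preprocessed series with the fitted prediction overlaid.
#'
#' @param x A [prf_fit()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prf_fit <- function(x, ...) {
  graphics::plot(x$data, type = "l", col = "grey40",
                 xlab = "volume", ylab = "normalized signal", ...)
  graphics::lines(x$fitted_values, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("observed", "fitted"),
                   col = c("grey40", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate replicate runs from a fitted pRF
#'
#' Generates `nsim` noisy replicate series from the fitted prediction
#' under an AR(1)-plus-drift noise model, on the preprocessed scale.
#'
#' @param object A [prf_fit()] result.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param noise A [noise_model()].
#' @param ... Unused.
#' @return Matrix nsim x volumes.
#' @export
simulate.prf_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_model(), ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted_values)
  out <- matrix(0, nsim, n)
  for (i in seq_len(nsim))
    out[i, ] <- object$fitted_values +
      .drift_and_noise(n, noise)
  out
}
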