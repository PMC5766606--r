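#' Double-gamma haemodynamic response specification
#'
#' Canonical difference-of-gammas impulse response linking neural activity
#' to the BOLD signal.  Each lobe is a gamma density parameterized by its
#' mode (`*_delay_s`) and dispersion, so the kernel peaks at
#' `peak_delay_s` and undershoots around `undershoot_delay_s`.
#'
#' @param peak_delay_s Time of the positive peak (s).
#' @param undershoot_delay_s Time of the undershoot trough (s).
#' @param peak_dispersion_s,undershoot_dispersion_s Gamma dispersions (s).
#' @param peak_undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param kernel_length_s Kernel support (s).
#' @param dt_s Sampling step of the kernel; must divide the TR.
#'
#' @return An object of class `"hrf_spec"`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     peak_undershoot_ratio = 6, kernel_length_s = 32,
                     dt_s = 0.1) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_dispersion_s,
            undershoot_dispersion_s, peak_undershoot_ratio,
            kernel_length_s, dt_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid HRF specification", call. = FALSE)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length_s = kernel_length_s,
                 dt_s = dt_s),
            class = "hrf_spec")
}

#' Sample the haemodynamic response kernel
#'
#' Evaluates the double-gamma kernel at `dt_s` resolution and normalizes
#' it to a maximum of 1 (absolute response scale is absorbed into the pRF
#' amplitude parameter beta).
#'
#' @param spec An [hrf_spec()].
#' @return Numeric vector of kernel samples at times
#'   `0, dt_s, 2 dt_s, ..., kernel_length_s`.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$kernel_length_s, by = spec$dt_s)
  # gamma density with mode m and dispersion d: shape = 1 + m/d, rate = 1/d
  lobe <- function(m, d) stats::dgamma(t, shape = 1 + m / d, rate = 1 / d)
  k <- lobe(spec$peak_delay_s, spec$peak_dispersion_s) -
    lobe(spec$undershoot_delay_s, spec$undershoot_dispersion_s) /
      spec$peak_undershoot_ratio
  k / max(k)
}

# Linear map from per-volume neural drive (all volumes, dummy included) to
# the BOLD prediction sampled at the onsets of the retained volumes.
# Equivalent to: hold the drive piecewise-constant over each TR, convolve
# with the kernel at dt resolution with a zero-padded (blank) history, and
# read off the convolution at each retained volume onset.  Precomputing
# the map makes per-candidate prediction a single matrix product.
.conv_matrix <- function(design, hrf = hrf_spec()) {
  ratio <- design$tr_s / hrf$dt_s
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("hrf dt_s must divide the TR", call. = FALSE)
  ratio <- as.integer(round(ratio))
  k <- hrf_kernel(hrf)
  n_total <- design$n_volumes_total
  n_ret <- design$n_volumes_retained
  W <- matrix(0, nrow = n_ret, ncol = n_total)
  for (j in seq_len(n_ret)) {
    m_j <- (design$n_volumes_dummy + j - 1L) * ratio  # onset sample index
    i <- seq_along(k) - 1L
    m <- m_j - i
    keep <- m >= 0L
    vols <- m[keep] %/% ratio + 1L          # volume owning each past sample
    w <- rowsum(k[keep] * hrf$dt_s, vols)
    W[j, as.integer(rownames(w))] <- w
  }
  W
}
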