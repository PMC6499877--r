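#' Canonical double-gamma haemodynamic response function
#'
#' The kernel linking neural drive to the BOLD signal: a gamma density
#' peaking at `peak_delay` seconds minus a `ratio`-scaled gamma density
#' peaking at `undershoot_delay` seconds, sampled at the repetition time
#' and normalised to unit peak.
#'
#' @param tr Sampling interval (repetition time) in seconds.
#' @param duration Kernel support in seconds.
#' @param peak_delay Time-to-peak of the positive lobe, seconds.
#' @param undershoot_delay Time-to-peak of the undershoot, seconds.
#' @param ratio Undershoot amplitude relative to the peak lobe.
#' @return An `hrf` object: the sampled kernel with a `tr` attribute.
#' @examples
#' h <- hrf_double_gamma(tr = 3)
#' which.max(h)  # sample nearest the 6 s peak
#' @export
hrf_double_gamma <- function(tr = 3, duration = 30, peak_delay = 6,
                             undershoot_delay = 16, ratio = 1 / 6) {
  stopifnot(tr > 0, duration > tr, peak_delay > 0, undershoot_delay > peak_delay,
            ratio >= 0)
  t <- seq(0, duration, by = tr)
  # gamma with rate 1 has mode (shape - 1), so shape = delay + 1
  h <- stats::dgamma(t, shape = peak_delay + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay + 1, rate = 1)
  if (sum(h) <= 0) stop("HRF kernel does not integrate to a positive value", call. = FALSE)
  h <- h / max(h)
  structure(h, tr = tr, class = c("hrf", "numeric"))
}

# Causal convolution of every row of `mat` (voxels x volumes) with the HRF
# kernel, truncated to the run length.  Implemented as one multiplication
# with an upper-banded Toeplitz matrix so that the same code path serves
# single time courses and whole populations.
convolve_hrf <- function(mat, hrf) {
  vec <- is.null(dim(mat))
  if (vec) mat <- matrix(mat, nrow = 1)
  out <- mat %*% hrf_conv_matrix(ncol(mat), hrf)
  if (vec) drop(out) else out
}
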