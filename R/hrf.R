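#' Canonical double-gamma hemodynamic response function
#'
#' Impulse response linking neural activity to the hemodynamic signal:
#' difference of two gamma densities with a peak near 6 s, an undershoot
#' near 16 s and an undershoot-to-peak ratio of 1/6, normalised to unit
#' peak amplitude.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s length of the sampled impulse response in seconds
#'   (default 32, enough for the undershoot to decay).
#' @param peak_s,undershoot_s gamma shape parameters (mode positions in
#'   seconds for rate 1).
#' @param undershoot_ratio amplitude ratio of the undershoot gamma.
#' @return numeric vector of `floor(duration_s * fs) + 1` samples.
#' @export
canonical_hrf <- function(fs, duration_s = 32, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6) {
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s, rate = 1)
  h / max(h)
}

# convolve a sampled stimulus series with the HRF, truncated to the input
# length (causal convolution)
.hrf_convolve <- function(x, hrf) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(hrf))), rev(hrf), type = "open")
  y[seq_len(n)]
}

# unit-peak task response shape: boxcar convolved with the HRF, scaled so a
# single trial peaks at 1.  The same scale is used by the GLM design so
# estimated betas are directly comparable to generator amplitudes.
.response_scale <- function(design, hrf) {
  one <- numeric(length(design$boxcar))
  i0 <- which(design$boxcar > 0)[1]
  len <- round(design$task_s * design$fs)
  one[seq(i0, min(i0 + len - 1, length(one)))] <- 1
  max(.hrf_convolve(one, hrf))
}
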