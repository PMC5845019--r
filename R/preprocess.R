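#' Preprocessing configuration
#'
#' Defaults follow the standard chain for slow block designs: median filter
#' of width 3 to knock out spikes, quadratic detrend for slow drift,
#' Z-scoring to cancel the unknown per-channel pathlength factor, and a
#' zero-phase 2nd-order Butterworth low-pass at 0.08 Hz that removes
#' cardiac and respiratory bands while keeping the 0.04 Hz block response.
#'
#' @param median_window odd window width (samples) of the median filter.
#' @param detrend_order polynomial order of the detrend.
#' @param lowpass_cutoff_hz low-pass cutoff in Hz (must be < fs/2).
#' @param filter_order Butterworth design order (applied forward and
#'   backward, so the effective magnitude response is squared).
#' @param zero_phase apply the filter forward-backward (TRUE) or forward
#'   only.
#' @param zscore divide each channel by its own SD after mean removal;
#'   disable only for calibration studies of raw-amplitude recovery.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(median_window = 3, detrend_order = 2,
                              lowpass_cutoff_hz = 0.08, filter_order = 2,
                              zero_phase = TRUE, zscore = TRUE) {
  if (median_window %% 2 != 1 || median_window < 1)
    stop("median_window must be an odd positive integer")
  if (detrend_order < 0) stop("detrend_order must be >= 0")
  if (lowpass_cutoff_hz <= 0) stop("lowpass_cutoff_hz must be positive")
  structure(list(median_window = median_window,
                 detrend_order = detrend_order,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 filter_order = filter_order, zero_phase = zero_phase,
                 zscore = zscore),
            class = "preprocess_config")
}

#' Sliding median filter
#'
#' Each sample is replaced by the median of its centred window.  At the
#' boundaries the window shrinks to the available samples (so the first
#' sample of a width-3 filter is the median of samples 1-2, i.e. their
#' mean).  Length is preserved.
#'
#' @param x numeric vector.
#' @param window odd positive window width.
#' @return filtered vector.
#' @export
median_filter <- function(x, window = 3) {
  if (window %% 2 != 1 || window < 1)
    stop("window must be an odd positive integer")
  n <- length(x)
  if (window > n) stop("window longer than the series")
  if (window == 1) return(x)
  if (window == 3) {
    # vectorised median-of-3 on the interior
    a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; c <- x[3:n]
    mid <- pmax(pmin(a, b), pmin(pmax(a, b), c))
    out <- c(mean(x[1:2]), mid, mean(x[(n - 1):n]))
    return(out)
  }
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Polynomial detrending
#'
#' Fits a polynomial of the given order to the full record by least
#' squares and subtracts it; the residual has zero projection on the
#' polynomial basis.
#'
#' @param x numeric vector (or channels x samples matrix: each row is
#'   detrended against the same basis).
#' @param order polynomial order (default 2, removing quadratic drift).
#' @return residual of the same shape as `x`.
#' @export
detrend_poly <- function(x, order = 2) {
  mat <- is.matrix(x)
  n <- if (mat) ncol(x) else length(x)
  if (n <= order + 1) stop("series too short for a degree-", order, " fit")
  B <- cbind(1, stats::poly(seq_len(n), degree = order))
  Q <- qr.Q(qr(B))
  if (mat) {
    t(t(x) - Q %*% crossprod(Q, t(x)))
  } else {
    as.numeric(x - Q %*% crossprod(Q, x))
  }
}

#' Z-score a series
#'
#' `(x - mean(x)) / sd_pop(x)` with the population SD (divide by N).  This
#' cancels any positive per-channel scale factor, in particular the
#' unknown photon pathlength: `zscore(c * x) == zscore(x)` for c > 0.
#'
#' @param x numeric vector, nonconstant.
#' @return standardized vector (mean 0, population SD 1).
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    stop("constant series: zero variance, channel is degenerate")
  (x - m) / s
}

#' Butterworth low-pass coefficients
#'
#' Digital low-pass by bilinear transform of the analog Butterworth
#' prototype with prewarped cutoff.  Returns transfer-function
#' coefficients normalised to `a[1] = 1`.
#'
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (>= 1).
#' @return list with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_lowpass <- function(cutoff, fs, order = 2) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  if (order < 1) stop("order must be >= 1")
  wc <- 2 * fs * tan(pi * cutoff / fs)      # prewarped analog cutoff
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z_poles <- (2 * fs + p_analog) / (2 * fs - p_analog)
  # expand prod(1 - p z^-1) to polynomial coefficients in z^-1
  a <- 1
  for (p in z_poles) a <- c(a, 0) - p * c(0, a)
  a <- Re(a)
  b <- choose(order, 0:order)               # zeros at z = -1
  b <- b * sum(a) / sum(b)                  # unit DC gain
  list(b = b, a = a)
}

# single-pass IIR filter with steady-state (DC) initial conditions for the
# level x[1]: equivalent to starting from an infinitely long constant
# history at x[1], so a constant input passes through unchanged.
.lfilter_ss <- function(x, b, a) {
  nb <- length(b)
  x0 <- x[1]
  xp <- c(rep(x0, nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[-seq_len(nb - 1)]
  y0 <- x0 * sum(b) / sum(a)                # DC output level
  y <- stats::filter(u, -a[-1], method = "recursive",
                     init = rep(y0, length(a) - 1))
  as.numeric(y)
}

#' Zero-phase (forward-backward) Butterworth low-pass
#'
#' Applies the filter forward and backward, cancelling the phase response;
#' the effective magnitude response is the square of the single-pass
#' design.  Edges are handled by odd-reflection padding plus steady-state
#' initial conditions (the filtfilt convention).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param order design order (default 2).
#' @param zero_phase if `FALSE`, a single forward pass is applied instead.
#' @return filtered vector, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 0.08, order = 2, zero_phase = TRUE) {
  co <- butter_lowpass(cutoff, fs, order)
  if (!zero_phase) return(.lfilter_ss(x, co$b, co$a))
  n <- length(x)
  padlen <- min(n - 1, 3 * length(co$a))
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- .lfilter_ss(c(pre, x, post), co$b, co$a)
  y <- rev(.lfilter_ss(rev(y), co$b, co$a))
  y[seq(padlen + 1, padlen + n)]
}

#' Preprocess a recording channel by channel
#'
#' Applies, in order: median filter, polynomial detrend, Z-score, low-pass.
#' Constant (dead) channels cannot be Z-scored; they are zeroed, flagged in
#' `recording$flags` and must be excluded from regressor construction and
#' statistics downstream.
#'
#' @param recording a `nirs_recording`.
#' @param config a [preprocess_config()].
#' @return the recording with processed `data` and updated `flags`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (config$lowpass_cutoff_hz >= recording$fs / 2)
    stop("low-pass cutoff must be below the Nyquist frequency")
  data <- recording$data
  flags <- recording$flags
  for (c in seq_len(nrow(data))) {
    x <- median_filter(data[c, ], config$median_window)
    s_raw <- stats::sd(x)
    x <- detrend_poly(x, config$detrend_order)
    # dead channel: constant, or nothing left beyond the fitted trend
    if (s_raw == 0 || stats::sd(x) <= 1e-12 * s_raw) {
      flags[c] <- TRUE
      data[c, ] <- 0
      next
    }
    if (config$zscore) x <- zscore(x)
    data[c, ] <- lowpass(x, recording$fs, config$lowpass_cutoff_hz,
                         config$filter_order, config$zero_phase)
  }
  recording$data <- data
  recording$flags <- flags
  recording
}
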