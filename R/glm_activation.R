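#' Per-trial GLM design matrix
#'
#' One regressor per trial: the trial's boxcar convolved with the HRF,
#' plus an intercept column and (optionally) a linear drift column.  All
#' trial columns share a common scale chosen so a single convolved trial
#' peaks at 1; betas on Z-scored data are then directly interpretable as
#' peak response amplitudes in Z units.
#'
#' @param design a [make_design()] object.
#' @param hrf HRF impulse response sampled at `design$fs` (default the
#'   canonical double-gamma).
#' @param drift add a linear drift column (off by default; detrending is
#'   done upstream).
#' @return samples x columns matrix of class `design_matrix` with
#'   attribute `labels`; trial columns first, then `intercept` (and
#'   `drift`).
#' @export
build_design <- function(design, hrf = canonical_hrf(design$fs),
                         drift = FALSE) {
  n <- length(design$boxcar)
  fs <- design$fs
  len <- round(design$task_s * fs)
  scale <- .response_scale(design, hrf)
  cols <- vector("list", design$n_trials)
  for (k in seq_len(design$n_trials)) {
    box_k <- numeric(n)
    i0 <- floor(design$onsets[k] * fs) + 1
    box_k[seq(i0, min(i0 + len - 1, n))] <- 1
    cols[[k]] <- .hrf_convolve(box_k, hrf) / scale
  }
  X <- do.call(cbind, cols)
  labels <- paste0("trial", seq_len(design$n_trials))
  X <- cbind(X, 1)
  labels <- c(labels, "intercept")
  if (drift) {
    X <- cbind(X, seq_len(n) / n)
    labels <- c(labels, "drift")
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (overlapping trial regressors?)")
  colnames(X) <- labels
  structure(X, labels = labels, n_trials = design$n_trials,
            class = c("design_matrix", "matrix", "array"))
}

#' Fit the GLM to one series
#'
#' Ordinary least squares `beta = (X'X)^-1 X'y`.  No prewhitening or
#' precoloring is applied.
#'
#' @param y numeric series (length = rows of `X`).
#' @param X a [build_design()] matrix.
#' @return list with `betas` (per-trial coefficients), `coef` (all
#'   coefficients), `sigma2` (residual variance, denominator n - p).
#' @export
fit_glm <- function(y, X) {
  if (length(y) != nrow(X)) stop("series length does not match the design")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  coef <- qr.coef(qrx, y)
  res <- y - as.numeric(X %*% coef)
  nt <- attr(X, "n_trials")
  list(betas = unname(coef[seq_len(nt)]), coef = coef,
       sigma2 = sum(res^2) / (length(y) - ncol(X)))
}

#' Average per-trial betas
#'
#' @param betas numeric vector of per-trial GLM coefficients.
#' @return their arithmetic mean.
#' @export
average_betas <- function(betas) {
  if (length(betas) < 1) stop("no trial betas to average")
  mean(betas)
}

#' Per-trial betas for every channel of a recording
#'
#' Fits the GLM once (shared QR decomposition) across all channels.
#' Flagged channels get `NA` betas.
#'
#' @param recording a preprocessed `nirs_recording`.
#' @param X a [build_design()] matrix.
#' @return data.frame with columns `subject`, `condition`, `channel`,
#'   `trial`, `beta`.
#' @export
fit_glm_recording <- function(recording, X) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (ncol(recording$data) != nrow(X))
    stop("recording length does not match the design")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  coef <- qr.coef(qrx, t(recording$data))   # p x channels
  nt <- attr(X, "n_trials")
  nc <- nrow(recording$data)
  betas <- t(coef[seq_len(nt), , drop = FALSE])  # channels x trials
  betas[recording$flags, ] <- NA_real_
  data.frame(
    subject = recording$subject_id,
    condition = recording$condition,
    channel = rep(seq_len(nc), times = nt),
    trial = rep(seq_len(nt), each = nc),
    beta = as.numeric(betas)
  )
}

#' Average a per-trial beta table over trials
#'
#' @param beta_table output of [fit_glm_recording()] (possibly several
#'   recordings row-bound together).
#' @return data.frame with one row per (subject, condition, channel) and a
#'   `beta` column holding the mean over trials.
#' @export
average_beta_table <- function(beta_table) {
  out <- stats::aggregate(beta ~ subject + condition + channel,
                          data = beta_table, FUN = mean, na.action = NULL)
  out[order(out$subject, out$condition, out$channel), , drop = FALSE]
}
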