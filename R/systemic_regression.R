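#' Correlation of a channel with the task function
#'
#' Pearson correlation between a channel's (preprocessed) series and the
#' 0/1 task boxcar.  A constant series has no defined correlation and is
#' returned as `NA` (flagged degenerate; such channels never enter
#' regressor construction).
#'
#' @param x numeric vector.
#' @param boxcar 0/1 task function of the same length.
#' @return correlation coefficient in `[-1, 1]`, or `NA` for a constant
#'   input.
#' @export
task_correlation <- function(x, boxcar) {
  if (length(x) != length(boxcar)) stop("series and boxcar lengths differ")
  if (stats::sd(boxcar) == 0) stop("boxcar is constant; invalid design")
  if (stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, boxcar)
}

#' Select task-unrelated channels
#'
#' Channels whose absolute task correlation is strictly below the
#' threshold (default 0.2).  Degenerate channels (`NA` correlation) are
#' excluded.
#'
#' @param r named or plain numeric vector of task correlations indexed by
#'   channel id.
#' @param threshold strict threshold on `|r|`, in (0, 1).
#' @param side_channels optional channel ids to restrict the selection to
#'   (e.g. one hemisphere).
#' @return integer vector of selected channel ids.
#' @export
select_task_unrelated <- function(r, threshold = 0.2, side_channels = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- seq_along(r)
  keep <- !is.na(r) & abs(r) < threshold
  if (!is.null(side_channels)) keep <- keep & ids %in% side_channels
  ids[keep]
}

#' Build the systemic regressor
#'
#' Pointwise mean of the selected channels' series.
#'
#' @param data channels x samples matrix.
#' @param selected channel ids (row indices), nonempty.
#' @return numeric vector (the regressor series).
#' @export
build_regressor <- function(data, selected) {
  if (length(selected) == 0) stop("no channels selected for the regressor")
  if (length(selected) == 1) return(data[selected, ])
  colMeans(data[selected, , drop = FALSE])
}

#' Regress a series on a systemic regressor
#'
#' Ordinary least squares of the series on `{intercept, regressor}`; the
#' residual is returned and is uncorrelated with the regressor.  A constant
#' regressor degenerates to mean removal.
#'
#' @param x numeric vector.
#' @param regressor numeric vector of the same length.
#' @return residual series, with attribute `coef` (the fitted slope, `NA`
#'   for a constant regressor).
#' @export
regress_out <- function(x, regressor) {
  if (length(x) != length(regressor))
    stop("series and regressor lengths differ")
  if (stats::sd(regressor) == 0) {
    out <- x - mean(x)
    attr(out, "coef") <- NA_real_
    return(out)
  }
  g <- regressor - mean(regressor)
  b <- sum(g * x) / sum(g * g)
  out <- x - mean(x) - b * g
  attr(out, "coef") <- b
  out
}

#' Hemispheric task-unrelated channel regression
#'
#' Steps 5-6 of the preprocessing chain.  For each hemisphere separately:
#' compute every channel's correlation with the task boxcar, select the
#' task-unrelated channels (`|r|` strictly below `threshold`) on that
#' side, average them into a regressor, and regress that regressor out of
#' every channel on the same side.  The left regressor is never applied to
#' the right hemisphere and vice versa.  If a side has no task-unrelated
#' channel the side is left untouched with a warning (the threshold is
#' never adapted).
#'
#' @param recording a preprocessed `nirs_recording`.
#' @param layout the `probe_layout` matching the recording's channels.
#' @param boxcar task function sampled at the recording's rate.
#' @param threshold strict selection threshold on `|r|` (default 0.2).
#' @param hrf_convolved correlate against the HRF-convolved boxcar instead
#'   of the raw boxcar (off by default; the raw boxcar is the reference
#'   method).
#' @param leave_one_out rebuild the regressor without the target channel
#'   when the target is itself task-unrelated (off by default; the
#'   reference method regresses the common regressor out of every channel,
#'   including those that contributed to it).
#' @return list with `recording` (residual series) and `report`, a list of
#'   class `regression_report` carrying per-channel `r`, the selected sets
#'   and regressors per side, fitted coefficients, and the before/after
#'   channel correlation matrices (the standard diagnostic for shared
#'   systemic interference).
#' @export
apply_hemispheric_regression <- function(recording, layout, boxcar,
                                         threshold = 0.2,
                                         hrf_convolved = FALSE,
                                         leave_one_out = FALSE) {
  stopifnot(inherits(recording, "nirs_recording"))
  data <- recording$data
  nc <- nrow(data)
  if (nc != nrow(layout$channels))
    stop("recording and layout disagree on the channel count")
  target <- boxcar
  if (hrf_convolved) {
    h <- canonical_hrf(recording$fs)
    target <- .hrf_convolve(boxcar, h)
  }
  r <- vapply(seq_len(nc), function(c) {
    if (recording$flags[c]) return(NA_real_)
    task_correlation(data[c, ], target)
  }, numeric(1))
  cor_before <- stats::cor(t(data))
  out <- data
  selected <- list(); regressors <- list()
  coefs <- rep(NA_real_, nc)
  for (side in c("left", "right")) {
    side_ids <- hemisphere_channels(layout, side)
    sel <- select_task_unrelated(r, threshold, side_ids)
    sel <- setdiff(sel, which(recording$flags))
    selected[[side]] <- sel
    if (length(sel) == 0) {
      warning("no task-unrelated channels on the ", side,
              " hemisphere; side left unregressed")
      regressors[[side]] <- NULL
      next
    }
    reg <- build_regressor(data, sel)
    regressors[[side]] <- reg
    for (c in side_ids) {
      if (recording$flags[c]) next
      this_reg <- reg
      if (leave_one_out && c %in% sel && length(sel) > 1)
        this_reg <- build_regressor(data, setdiff(sel, c))
      res <- regress_out(data[c, ], this_reg)
      coefs[c] <- attr(res, "coef")
      out[c, ] <- as.numeric(res)
    }
  }
  recording$data <- out
  report <- structure(
    list(r = r, threshold = threshold, selected = selected,
         regressors = regressors, coef = coefs,
         cor_before = cor_before, cor_after = stats::cor(t(out))),
    class = "regression_report"
  )
  list(recording = recording, report = report)
}

#' Mean absolute off-diagonal correlation
#'
#' Summary used to quantify shared systemic interference before and after
#' regression.
#'
#' @param cmat square correlation matrix.
#' @param channels optional subset of channel indices.
#' @return mean of `|r|` over off-diagonal entries; undefined entries
#'   (e.g. from constant residual channels) are ignored.
#' @export
mean_offdiag_cor <- function(cmat, channels = NULL) {
  if (!is.null(channels)) cmat <- cmat[channels, channels, drop = FALSE]
  mean(abs(cmat[row(cmat) != col(cmat)]), na.rm = TRUE)
}

#' Correlation-map diagnostic figure
#'
#' Writes a side-by-side heat map of the channel correlation matrices
#' before and after regression.
#'
#' @param report a `regression_report`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plot_correlation_maps <- function(report, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (nm in c("cor_before", "cor_after")) {
    m <- report[[nm]]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    zlim = c(-1, 1), col = pal, xlab = "channel",
                    ylab = "channel",
                    main = if (nm == "cor_before") "before regression"
                           else "after regression")
  }
  invisible(path)
}
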