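#' One-sample t-test
#'
#' `t = mean(x) / (sd(x) / sqrt(n))` with `df = n - 1` (sample SD).
#'
#' @param x numeric vector across subjects, `n >= 2`, nonzero variance.
#' @param mu null value (default 0).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`.
#' @export
one_sample_t <- function(x, mu = 0,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least two observations")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: t statistic undefined")
  t <- (mean(x) - mu) / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' rejects hypotheses `1..k*` where `k*` is the largest `k` with
#' `p_(k) <= k q / m`.  Adjusted p-values are
#' `min over j >= k of p_(j) m / j`, so `p_adj <= q` reproduces the
#' rejection set.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   ignored).
#' @param q target FDR level for the significance flags (default 0.05).
#' @return list with `p_adj` and logical `significant` (both aligned with
#'   the input).
#' @export
fdr_bh <- function(p, q = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  p_adj <- rep(NA_real_, length(p))
  sig <- rep(NA, length(p))
  if (m > 0) {
    pv <- p[ok]
    o <- order(pv)
    adj <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
    p_adj[ok][o] <- adj
    # step-up rejection set
    k_star <- max(c(0, which(pv[o] <= seq_len(m) * q / m)))
    sg <- logical(m)
    if (k_star > 0) sg[o[seq_len(k_star)]] <- TRUE
    sig[ok] <- sg
  }
  list(p_adj = p_adj, significant = sig)
}

#' Per-channel group activation statistics
#'
#' For each condition and channel, a one-sample t-test of the subjects'
#' mean betas against zero, followed by Benjamini-Hochberg FDR correction
#' across the channels of that condition.  A channel is flagged
#' `activated` when it survives FDR at level `q` *and* its t is positive
#' (activation = increase in HbO2).
#'
#' @param avg_betas averaged beta table from [average_beta_table()].
#' @param q FDR level (default 0.05).
#' @param alternative tail convention for the t-tests (default two-sided).
#' @return data.frame of class `group_activation` with columns
#'   `condition`, `channel`, `n`, `t`, `df`, `p_raw`, `p_fdr`,
#'   `significant`, `activated`.
#' @export
group_activation <- function(avg_betas, q = 0.05,
                             alternative = "two.sided") {
  out <- list()
  for (cond in unique(avg_betas$condition)) {
    sub <- avg_betas[avg_betas$condition == cond, , drop = FALSE]
    channels <- sort(unique(sub$channel))
    rows <- lapply(channels, function(ch) {
      vals <- sub$beta[sub$channel == ch]
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2 || stats::sd(vals) == 0)
        return(data.frame(condition = cond, channel = ch,
                          n = length(vals), t = NA_real_, df = NA_real_,
                          p_raw = NA_real_))
      tt <- one_sample_t(vals, alternative = alternative)
      data.frame(condition = cond, channel = ch, n = length(vals),
                 t = tt$t, df = tt$df, p_raw = tt$p)
    })
    tab <- do.call(rbind, rows)
    fdr <- fdr_bh(tab$p_raw, q)
    tab$p_fdr <- fdr$p_adj
    tab$significant <- fdr$significant
    tab$activated <- !is.na(tab$significant) & tab$significant & tab$t > 0
    out[[cond]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("group_activation", "data.frame")
  res
}

#' Per-ROI mean betas
#'
#' Mean of the averaged channel betas over each ROI's channels, per
#' subject and condition.
#'
#' @param avg_betas averaged beta table from [average_beta_table()].
#' @param layout a `probe_layout` with ROIs assigned.
#' @return data.frame with columns `subject`, `condition`, `roi`,
#'   `hemisphere`, `beta`.
#' @export
roi_means <- function(avg_betas, layout) {
  ch <- layout$channels
  keep <- ch$roi != "none"
  if (!any(keep)) stop("layout has no ROI labels; run assign_rois() first")
  map <- ch[keep, c("id", "roi", "hemisphere")]
  merged <- merge(avg_betas, map, by.x = "channel", by.y = "id")
  out <- stats::aggregate(beta ~ subject + condition + roi + hemisphere,
                          data = merged, FUN = mean)
  out[order(out$subject, out$condition, out$roi, out$hemisphere), ,
      drop = FALSE]
}

#' 2x2 repeated-measures ANOVA
#'
#' Within-subject factors task (ME vs MI) and hand (left vs right).  For
#' each effect (task, hand, interaction) the F ratio is the effect mean
#' square over the effect-by-subject interaction mean square, with
#' `df = (1, n - 1)`; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.  With both factors at two levels
#' every effect has one numerator df, so sphericity holds trivially and
#' each main-effect F equals the square of the paired t on the factor's
#' margins.
#'
#' @param data data.frame with columns `subject`, `task`, `hand`, `value`;
#'   exactly one value per subject x task x hand cell.
#' @return data.frame with columns `effect`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
repeated_anova_2x2 <- function(data) {
  need <- c("subject", "task", "hand", "value")
  if (!all(need %in% names(data))) stop("data must have columns ",
                                        paste(need, collapse = ", "))
  tasks <- sort(unique(data$task)); hands <- sort(unique(data$hand))
  subjects <- unique(data$subject)
  if (length(tasks) != 2 || length(hands) != 2)
    stop("task and hand must each have exactly two levels")
  n <- length(subjects)
  if (n < 2) stop("need at least two subjects")
  # y[subject, task, hand]
  y <- array(NA_real_, c(n, 2, 2))
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2) {
    v <- data$value[data$subject == subjects[i] & data$task == tasks[a] &
                      data$hand == hands[b]]
    if (length(v) != 1) stop("design must be complete with one value per ",
                             "subject x task x hand cell")
    y[i, a, b] <- v
  }
  grand <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) -
                      outer(rep(1, 2), m_b) + grand)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + grand)^2)
  resid <- y
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2)
    resid[i, a, b] <- y[i, a, b] - m_ab[a, b] - m_sa[i, a] - m_sb[i, b] +
      m_a[a] + m_b[b] + m_s[i] - grand
  ss_abs <- sum(resid^2)
  row <- function(effect, ss_eff, ss_err) {
    df2 <- n - 1
    if (ss_eff == 0) {
      # degenerate case (includes 0/0 when the error term also vanishes)
      return(data.frame(effect = effect, F = 0, df1 = 1, df2 = df2,
                        p = 1, partial_eta_sq = 0))
    }
    Fv <- (ss_eff / 1) / (ss_err / df2)
    data.frame(effect = effect, F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + ss_err))
  }
  out <- rbind(row("task", ss_a, ss_as),
               row("hand", ss_b, ss_bs),
               row("task:hand", ss_ab, ss_abs))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected paired post hoc t-tests
#'
#' Each comparison is a paired t-test; the mean difference (MD) is the
#' mean within-subject difference and adjusted p-values are the raw
#' p-values multiplied by the number of comparisons, clipped at 1.
#'
#' @param data data.frame with columns `subject`, `cell` (condition
#'   label), `value`.
#' @param comparisons list of length-2 character vectors naming cell
#'   levels to compare (first minus second).
#' @return data.frame with columns `comparison`, `MD`, `t`, `df`, `p_raw`,
#'   `p_bonf`.
#' @export
posthoc_paired <- function(data, comparisons) {
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    a <- data[data$cell == cmp[1], c("subject", "value")]
    b <- data[data$cell == cmp[2], c("subject", "value")]
    merged <- merge(a, b, by = "subject")
    if (nrow(merged) < 2) stop("need at least two paired observations")
    d <- merged$value.x - merged$value.y
    if (stats::sd(d) == 0) {
      tt <- list(t = 0, df = nrow(merged) - 1, p = 1)
    } else {
      tt <- one_sample_t(d)
    }
    data.frame(comparison = paste(cmp[1], "vs", cmp[2]), MD = mean(d),
               t = tt$t, df = tt$df, p_raw = tt$p,
               p_bonf = min(1, tt$p * m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROI-wise 2x2 repeated ANOVA over all ROIs
#'
#' Runs [repeated_anova_2x2()] per ROI x hemisphere using the four
#' conditions (`ME_left`, `ME_right`, `MI_left`, `MI_right`).
#'
#' @param roi_table output of [roi_means()] containing all four
#'   conditions.
#' @return data.frame with `roi`, `hemisphere` and the ANOVA columns.
#' @export
anova_by_roi <- function(roi_table) {
  cond <- roi_table$condition
  roi_table$task <- ifelse(grepl("^ME", cond), "ME", "MI")
  roi_table$hand <- ifelse(grepl("left$", cond), "left", "right")
  out <- list()
  for (roi in unique(roi_table$roi)) {
    for (side in unique(roi_table$hemisphere[roi_table$roi == roi])) {
      sub <- roi_table[roi_table$roi == roi & roi_table$hemisphere == side, ]
      tab <- repeated_anova_2x2(data.frame(subject = sub$subject,
                                           task = sub$task, hand = sub$hand,
                                           value = sub$beta))
      tab <- cbind(roi = roi, hemisphere = side, tab)
      out[[paste(roi, side)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Channel t-map table and figure
#'
#' Emits the per-channel t/p/flag table for one condition and, if a path
#' is given, writes a grid heat map of t values keyed by the channel
#' midpoints.
#'
#' @param activation a [group_activation()] table.
#' @param layout the `probe_layout`.
#' @param condition condition to map (default: the first one present).
#' @param path optional PNG output path.
#' @return the per-channel table (invisibly the same data as the input,
#'   one condition, with channel coordinates attached).
#' @export
make_tmap <- function(activation, layout, condition = NULL, path = NULL) {
  if (is.null(condition)) condition <- activation$condition[1]
  tab <- activation[activation$condition == condition, , drop = FALSE]
  tab <- merge(tab, layout$channels[, c("id", "x_cm", "y_cm")],
               by.x = "channel", by.y = "id")
  tab <- tab[order(tab$channel), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 500)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(64, "Blue-Red 3")
    rng <- max(abs(tab$t), na.rm = TRUE)
    idx <- findInterval(tab$t, seq(-rng, rng, length.out = 65),
                        all.inside = TRUE)
    graphics::plot(tab$x_cm, -tab$y_cm, pch = 22, cex = 4,
                   bg = pal[idx], xlab = "x (cm)", ylab = "-y (cm)",
                   main = paste("t map:", condition))
    graphics::text(tab$x_cm, -tab$y_cm, tab$channel, cex = 0.7)
    sig <- tab$activated %in% TRUE
    if (any(sig))
      graphics::points(tab$x_cm[sig], -tab$y_cm[sig], pch = 0, cex = 5,
                       lwd = 2)
  }
  tab
}
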