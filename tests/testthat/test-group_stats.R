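test_that("one-sample t reproduces hand computations and the stats oracle", {
  expect_equal(one_sample_t(c(-1, 1))$t, 0)
  h <- one_sample_t(c(1, 2, 3))
  expect_equal(h$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)   # sample sd = 1
  expect_equal(h$df, 2)
  set.seed(61)
  for (rep in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    mine <- one_sample_t(x)
    ref <- stats::t.test(x)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(one_sample_t(rnorm(16))$df, 15)
  expect_error(one_sample_t(1), "at least two")
  expect_error(one_sample_t(c(2, 2, 2)), "zero variance")
})

test_that("BH-FDR matches the brute-force step-up oracle", {
  expect_equal(fdr_bh(0.03)$p_adj, 0.03)
  same <- fdr_bh(rep(0.04, 7))
  expect_equal(same$p_adj, rep(0.04, 7))      # min over k of p*m/k at k=m
  expect_true(all(same$significant))
  set.seed(62)
  for (rep in 1:100) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)
    res <- fdr_bh(p, q = 0.05)
    expect_equal(res$significant, naive_bh_flags(p, 0.05))
    expect_equal(res$p_adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # flags from adjusted p agree with the step-up rejection set
    expect_equal(res$significant, res$p_adj <= 0.05)
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH-FDR controls the expected false-discovery proportion under the null", {
  set.seed(63)
  n_groups <- 200
  fdp <- vapply(seq_len(n_groups), function(i) {
    betas <- matrix(rnorm(16 * 31), 16, 31)    # global null group
    p <- apply(betas, 2, function(v) one_sample_t(v)$p)
    flags <- fdr_bh(p, q = 0.05)$significant
    if (any(flags)) 1 else 0                   # all discoveries are false
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_groups))
})

test_that("roi_means aggregates exactly the ROI channel lists", {
  lay <- default_layout
  avg <- data.frame(subject = "S01", condition = "ME_left", channel = 1:31,
                    beta = as.numeric(1:31))
  rm_ <- roi_means(avg, lay)
  pfc_l <- rm_$beta[rm_$roi == "PFC" & rm_$hemisphere == "left"]
  expect_equal(pfc_l, mean(c(1, 2, 5, 6)))
  m1_r <- rm_$beta[rm_$roi == "M1" & rm_$hemisphere == "right"]
  expect_equal(m1_r, mean(c(18, 21, 22)))
  # single-channel and constant cases
  avg2 <- avg; avg2$beta <- rep(4, 31)
  rm2 <- roi_means(avg2, lay)
  expect_true(all(rm2$beta == 4))
  bare <- build_layout(4, 5)
  expect_error(roi_means(avg, bare), "no ROI labels")
})

test_that("2x2 repeated ANOVA: F = t^2 identity and aov oracle", {
  set.seed(64)
  for (rep in 1:100) {
    n <- sample(5:16, 1)
    d <- expand.grid(subject = seq_len(n), task = c("ME", "MI"),
                     hand = c("left", "right"))
    d$value <- rnorm(nrow(d)) + rep(rnorm(n), 4)
    tab <- repeated_anova_2x2(d)
    # main-effect F equals the square of the paired t on the margins
    for (fac in c("task", "hand")) {
      lv <- unique(d[[fac]])
      a <- tapply(d$value[d[[fac]] == lv[1]], d$subject[d[[fac]] == lv[1]], mean)
      b <- tapply(d$value[d[[fac]] == lv[2]], d$subject[d[[fac]] == lv[2]], mean)
      tt <- stats::t.test(a, b, paired = TRUE)
      expect_equal(tab$F[tab$effect == fac], unname(tt$statistic)^2,
                   tolerance = 1e-8)
      expect_equal(tab$p[tab$effect == fac], tt$p.value, tolerance = 1e-8)
    }
  }
  # independent oracle: stats::aov with an Error() stratum
  set.seed(65)
  n <- 10
  d <- expand.grid(subject = factor(seq_len(n)), task = c("ME", "MI"),
                   hand = c("left", "right"))
  d$value <- rnorm(nrow(d)) + ifelse(d$task == "ME", 0.5, 0)
  tab <- repeated_anova_2x2(d)
  fit <- stats::aov(value ~ task * hand + Error(subject / (task * hand)),
                    data = d)
  sm <- summary(fit)
  get_f <- function(stratum, term) {
    s <- sm[[stratum]][[1]]
    s[trimws(rownames(s)) == term, "F value"]
  }
  expect_equal(tab$F[tab$effect == "task"], get_f("Error: subject:task", "task"),
               tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "hand"], get_f("Error: subject:hand", "hand"),
               tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "task:hand"],
               get_f("Error: subject:task:hand", "task:hand"), tolerance = 1e-8)
})

test_that("ANOVA degenerate and invariance properties", {
  n <- 8
  d <- expand.grid(subject = seq_len(n), task = c("ME", "MI"),
                   hand = c("left", "right"))
  d$value <- rep(rnorm(n), 4)        # four conditions identical per subject
  tab <- repeated_anova_2x2(d)
  expect_equal(tab$F, rep(0, 3))
  expect_equal(tab$partial_eta_sq, rep(0, 3))
  # partial eta squared is invariant under affine response transforms
  set.seed(66)
  d$value <- rnorm(nrow(d))
  t1 <- repeated_anova_2x2(d)
  d2 <- d; d2$value <- 3.2 * d$value + 11
  t2 <- repeated_anova_2x2(d2)
  expect_equal(t1$partial_eta_sq, t2$partial_eta_sq, tolerance = 1e-10)
  expect_equal(t1$F, t2$F, tolerance = 1e-10)
  d3 <- d[-1, ]
  expect_error(repeated_anova_2x2(d3), "complete")
})

test_that("ANOVA rejection rates are calibrated by Monte Carlo", {
  set.seed(67)
  n_rep <- 200
  reject <- matrix(FALSE, n_rep, 2)
  for (i in seq_len(n_rep)) {
    n <- 16
    d <- expand.grid(subject = seq_len(n), task = c("ME", "MI"),
                     hand = c("left", "right"))
    base <- rep(rnorm(n, 0, 0.5), 4)
    null_val <- base + rnorm(nrow(d), 0, 0.3)
    alt_val <- null_val + ifelse(d$task == "ME", 0.3, 0)  # known task effect
    reject[i, 1] <- repeated_anova_2x2(transform(d, value = null_val)
                                       )$p[1] < 0.05
    reject[i, 2] <- repeated_anova_2x2(transform(d, value = alt_val)
                                       )$p[1] < 0.05
  }
  expect_lt(mean(reject[, 1]), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(mean(reject[, 2]), 0.5)   # well above the nominal rate
})

test_that("Bonferroni post hocs multiply and clip", {
  d <- data.frame(subject = rep(1:6, 2),
                  cell = rep(c("A", "B"), each = 6),
                  value = c(1:6, 1:6))
  same <- posthoc_paired(d, list(c("A", "B")))
  expect_equal(same$MD, 0)
  expect_equal(same$p_bonf, 1)
  set.seed(68)
  d$value <- rnorm(12)
  one <- posthoc_paired(d, list(c("A", "B")))
  expect_equal(one$p_bonf, one$p_raw)          # single comparison
  two <- posthoc_paired(rbind(d, transform(d, cell = paste0(cell, "2"))),
                        list(c("A", "B"), c("A2", "B2")))
  expect_equal(two$p_bonf, pmin(1, two$p_raw * 2))
})

test_that("group activation flags positive FDR-surviving channels only", {
  set.seed(69)
  avg <- expand.grid(subject = sprintf("S%02d", 1:16),
                     condition = "ME_left", channel = 1:31)
  avg$beta <- rnorm(nrow(avg), 0, 0.1)
  avg$beta[avg$channel == 5] <- avg$beta[avg$channel == 5] + 1   # active
  avg$beta[avg$channel == 9] <- avg$beta[avg$channel == 9] - 1   # deactive
  act <- group_activation(avg)
  expect_s3_class(act, "group_activation")
  expect_equal(act$df, rep(15, 31))
  r5 <- act[act$channel == 5, ]; r9 <- act[act$channel == 9, ]
  expect_true(r5$significant && r5$activated)
  expect_true(r9$significant && !r9$activated)     # negative t never "activated"
  expect_true(all(act$p_fdr >= act$p_raw, na.rm = TRUE))
})

test_that("t-map table round-trips through text and marks coordinates", {
  set.seed(70)
  avg <- expand.grid(subject = sprintf("S%02d", 1:8),
                     condition = "ME_left", channel = 1:31)
  avg$beta <- rnorm(nrow(avg))
  act <- group_activation(avg)
  png_path <- withr::local_tempfile(fileext = ".png")
  tab <- make_tmap(act, default_layout, path = png_path)
  expect_true(file.exists(png_path))
  expect_equal(nrow(tab), 31)
  expect_true(all(c("x_cm", "y_cm") %in% names(tab)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$activated, tab$activated)
  expect_equal(back$t, tab$t, tolerance = 1e-6)
})
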