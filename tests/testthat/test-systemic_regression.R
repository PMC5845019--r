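test_that("task correlation reproduces its defining cases", {
  des <- make_design(4, 10, 15, fs = 1, lead_in_s = 0)
  box <- des$boxcar
  expect_equal(task_correlation(box, box), 1)
  expect_equal(task_correlation(-box, box), -1)
  # sinusoid at half the block frequency over whole periods: alternate
  # blocks cancel, so the correlation vanishes
  t <- seq_along(box) - 1
  s <- sin(2 * pi * des$block_freq_hz / 2 * t)
  expect_lt(abs(task_correlation(s, box)), 0.05)
  expect_true(is.na(task_correlation(rep(1, length(box)), box)))
  expect_error(task_correlation(box, rep(0, length(box))), "constant")
  expect_error(task_correlation(box[-1], box), "lengths differ")
})

test_that("task-unrelated selection thresholds strictly at |r| < 0.2", {
  r <- c(0.05, 0.5, -0.19)
  expect_equal(select_task_unrelated(r), c(1L, 3L))
  expect_length(select_task_unrelated(c(0.3, -0.8, 0.21)), 0)
  expect_length(select_task_unrelated(c(0.2, -0.2)), 0)   # boundary excluded
  expect_equal(select_task_unrelated(c(0.1, NA, 0.15), side_channels = 1:3),
               c(1L, 3L))
  expect_equal(select_task_unrelated(c(0.1, 0.1, 0.1), side_channels = 2:3),
               2:3)
  expect_error(select_task_unrelated(r, threshold = 1.2), "threshold")
})

test_that("regressor construction and removal follow OLS", {
  m <- rbind(1:10, -(1:10), rnorm(10))
  expect_equal(build_regressor(m, 3), m[3, ])
  expect_equal(build_regressor(m, 1:2), rep(0, 10))
  expect_equal(build_regressor(rbind(m[1, ], m[1, ], m[1, ]), 1:3), m[1, ])
  expect_error(build_regressor(m, integer(0)), "no channels")

  x <- rnorm(50)
  res <- regress_out(x, x)
  expect_lt(max(abs(res)), 1e-10)
  # orthogonal regressor: only the mean is removed
  set.seed(41)
  g <- rnorm(100)
  y <- rnorm(100)
  y_perp <- y - sum((g - mean(g)) * y) / sum((g - mean(g))^2) * (g - mean(g))
  expect_equal(as.numeric(regress_out(y_perp, g)), y_perp - mean(y_perp))
  # residuals are uncorrelated with the regressor (OLS property)
  for (rep in 1:100) {
    a <- rnorm(30); b <- rnorm(30)
    expect_lt(abs(stats::cor(as.numeric(regress_out(a, b)), b)), 1e-8)
  }
  # constant regressor: mean removal only
  cst <- regress_out(y, rep(2, 100))
  expect_equal(as.numeric(cst), y - mean(y))
  expect_true(is.na(attr(cst, "coef")))
})

test_that("hemispheric regression never crosses the midline and decorrelates", {
  lay <- default_layout
  des <- small_design()
  n <- length(des$boxcar)
  # null recording dominated by one shared slow sinusoid
  set.seed(42)
  shared <- sin(2 * pi * 0.03 * des$time)
  data <- matrix(0, 31, n)
  for (c in 1:31) data[c, ] <- runif(1, 0.5, 1.5) * shared + rnorm(n, 0, 0.2)
  rec <- new_recording(data, des$fs)
  rec <- preprocess_recording(rec)
  out <- apply_hemispheric_regression(rec, lay, des$boxcar)
  rep_ <- out$report
  expect_lt(mean_offdiag_cor(rep_$cor_after),
            mean_offdiag_cor(rep_$cor_before) / 2)
  expect_true(all(rep_$selected$left %in% hemisphere_channels(lay, "left")))
  expect_true(all(rep_$selected$right %in% hemisphere_channels(lay, "right")))
})

test_that("regression is a near no-op without systemic coupling", {
  lay <- default_layout
  des <- small_design()
  set.seed(43)
  data <- matrix(rnorm(31 * length(des$boxcar)), 31)
  rec <- new_recording(data, des$fs)
  out <- apply_hemispheric_regression(rec, lay, des$boxcar)
  # independent channels: each output stays close to its mean-removed input
  # (the only change is removal of the channel's own 1/m share of the
  # regressor plus a weak chance fit)
  for (c in 1:31)
    expect_gt(stats::cor(out$recording$data[c, ], data[c, ]), 0.9)
  # exact OLS reconstruction identity
  recon <- t(sapply(1:31, function(c) {
    reg <- out$report$regressors[[lay$channels$hemisphere[c]]]
    data[c, ] - mean(data[c, ]) -
      out$report$coef[c] * (reg - mean(reg))
  }))
  expect_equal(unname(out$recording$data), recon, tolerance = 1e-10)
})

test_that("co-active channels stay correlated while null channels decorrelate", {
  lay <- default_layout
  des <- make_design(n_trials = 8)
  active <- roi_channels(lay, "SMC", "right")
  tr <- ground_truth(lay, active_channels = active, response_amplitude = 2,
                     noise_sd = 0.2, local_vlf_amp = 0.5)
  sim <- simulate_recording(lay, des, tr, systemic_params(), seed = 44)
  rec <- preprocess_recording(sim$recording)
  out <- apply_hemispheric_regression(rec, lay, des$boxcar)
  rep_ <- out$report
  act_cor <- mean_offdiag_cor(rep_$cor_after, active)
  null_right <- setdiff(hemisphere_channels(lay, "right"), active)
  null_cor <- mean_offdiag_cor(rep_$cor_after, null_right)
  expect_gt(act_cor, 0.6)
  expect_gt(act_cor, null_cor + 0.2)
})

test_that("empty selection skips the hemisphere with a warning", {
  lay <- default_layout
  des <- small_design()
  n <- length(des$boxcar)
  # every channel strongly task-correlated
  data <- outer(seq(0.5, 2, length.out = 31), des$boxcar) +
    matrix(rnorm(31 * n, 0, 0.01), 31)
  rec <- new_recording(data, des$fs)
  expect_warning(
    expect_warning(out <- apply_hemispheric_regression(rec, lay, des$boxcar),
                   "no task-unrelated channels"),
    "no task-unrelated channels")
  # untouched hemisphere data pass through unchanged
  expect_equal(out$recording$data, data)
})
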