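test_that("the canonical HRF kernel has the expected shape", {
  h <- hrf_kernel(0.5)
  t <- seq(0, 32, by = 0.5)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gte(peak, 5); expect_lte(peak, 6)
  # late undershoot is negative and small
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.3)
  # convolution with a unit impulse reproduces the kernel
  imp <- c(1, rep(0, 99))
  conv <- convolve(imp, rev(h), type = "open")[1:100]
  expect_equal(conv[seq_along(h)], h)
})

test_that("condition regressors are linear and periodic for block designs", {
  tr <- 2.2; n_tr <- 200
  # zero-duration event: regressor proportional to the shifted HRF
  d0 <- task_design(data.frame(onset = 44, duration = 0, trial_type = "a"))
  r0 <- dynstates:::condition_regressors_tr(d0, tr, n_tr)
  h <- hrf_kernel(tr)
  onset_idx <- floor(44 / tr) + 1
  expect_equal(unname(r0[1, onset_idx:(onset_idx + length(h) - 1)]), h)
  # two non-adjacent blocks superpose linearly
  one <- function(on) task_design(data.frame(onset = on, duration = 11,
                                             trial_type = "a"))
  both <- task_design(data.frame(onset = c(44, 220), duration = 11,
                                 trial_type = "a"))
  rb <- dynstates:::condition_regressors_tr(both, tr, n_tr)
  r1 <- dynstates:::condition_regressors_tr(one(44), tr, n_tr)
  r2 <- dynstates:::condition_regressors_tr(one(220), tr, n_tr)
  expect_equal(rb, r1 + r2)
  # periodic block design: autocorrelation peaks at the block period
  des <- block_design(conditions = "a", block_s = 22, rest_s = 22,
                      total_s = 200 * tr, start_s = 11)
  reg <- convolve_conditions(des, tr, n_tr, 8)
  ac <- acf(reg[1, ], lag.max = 30, plot = FALSE)$acf[-1]
  period_tr <- round(44 / tr)
  # local autocorrelation peak at the block period, trough at half period
  expect_gt(ac[period_tr], ac[round(period_tr / 2)])
  expect_gt(ac[period_tr], 0.5)
  expect_gt(ac[period_tr], ac[period_tr - 3])
  expect_gt(ac[period_tr], ac[period_tr + 3])
  # events beyond the scan end are truncated with a warning
  late <- task_design(data.frame(onset = 500, duration = 5, trial_type = "a"))
  expect_warning(dynstates:::condition_regressors_tr(late, tr, n_tr),
                 "beyond scan end")
})

test_that("group modulation recovers exact coupling and flags missing states", {
  set.seed(6)
  W <- 100
  reg <- matrix(sin(seq_len(W) / 6) + 1.2, 1, W,
                dimnames = list("drive", NULL))
  # occurrence proportional to the regressor: r = 1, minimal p
  A <- matrix(1L, 40, W)
  hi <- reg[1, ] > median(reg[1, ])
  A[1:20, hi] <- 2L
  gm <- group_modulation(A, reg, n_perm = 200, seed = 1, k = 2)
  expect_gt(gm$r["state2", "drive"], 0.8)
  expect_equal(min(gm$table$p), 1 / 201)
  # a never-present state yields a missing cell, excluded from FDR
  gm3 <- group_modulation(A, reg, n_perm = 50, seed = 1, k = 3)
  expect_true(is.na(gm3$table$r[gm3$table$state == 3]))
  expect_true(is.na(gm3$table$q_value[gm3$table$state == 3]))
})

test_that("Pearson-Filon z matches symmetry, sign, and a Monte-Carlo oracle", {
  expect_equal(pearson_filon_z(0.4, 0.4, 0.2, 100)$z, 0)
  expect_gt(pearson_filon_z(0.5, 0.3, 0.2, 100)$z, 0)
  expect_lt(pearson_filon_z(0.1, 0.3, 0.2, 100)$z, 0)
  expect_error(pearson_filon_z(1, 0.3, 0.2, 100), "correlations")
  expect_error(pearson_filon_z(0.5, 0.3, 0.2, 4), "n must exceed")

  # Monte-Carlo oracle: empirical SD of r_ac - r_bc under a trivariate
  # normal matches the implied standard error within 10 percent
  set.seed(31)
  Sig <- matrix(c(1, 0.3, 0.4,
                  0.3, 1, 0.5,
                  0.4, 0.5, 1), 3)
  ch <- chol(Sig)
  n <- 500
  diffs <- replicate(400, {
    X <- matrix(rnorm(n * 3), n) %*% ch
    cor(X[, 1], X[, 3]) - cor(X[, 2], X[, 3])
  })
  z1 <- pearson_filon_z(0.4, 0.5, 0.3, n)$z
  implied_se <- (0.4 - 0.5) / z1 / sqrt(1)
  expect_lt(abs(sd(diffs) - implied_se) / implied_se, 0.1)
})

test_that("partial correlations reduce correctly and support group inference", {
  set.seed(41)
  W <- 120
  reg <- rbind(a = sin(seq_len(W) / 5), b = cos(seq_len(W) / 7))
  A <- matrix(sample(1:2, 10 * W, replace = TRUE), 10, W)
  im <- individual_modulation(A, reg, k = 2)
  # no controls: partial r equals plain r (single-condition design)
  im1 <- individual_modulation(A, reg[1, , drop = FALSE], k = 2)
  plain <- cor(as.numeric(A[1, ] == 1), reg[1, ])
  expect_equal(unname(im1$r[1, 1, 1]), plain)
  # control identical to the target: partial r missing or zero
  regd <- rbind(a = reg[1, ], b = reg[1, ])
  imd <- individual_modulation(A, regd, k = 2)
  expect_true(all(is.na(imd$r[, , 1]) | abs(imd$r[, , 1]) < 1e-8))
  # constant indicator: subject excluded
  A2 <- A; A2[3, ] <- 1L
  im2 <- individual_modulation(A2, reg, k = 2)
  expect_equal(im2$table$n_excluded[im2$table$state == 2][1], 1L)
})

test_that("engaged-state coupling is detected at the individual level", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    cfg <- synthetic_config(n_subjects = 25, n_components = 4,
      state_covariances = make_block_covariances(4, 4),
      task_coupling = 2, seed = s)
    des <- event_design(conditions = c("go", "stop"), n_events = 15,
                        duration_s = 1.5, total_s = 440, seed = s)
    drive <- dynstates:::task_drive(cfg, des)
    A <- t(vapply(1:25, function(i)
      dynstates:::sample_state_chain(cfg, drive)[5:196], integer(192)))
    reg <- convolve_conditions(des, 2.2, 200, 8)
    im <- individual_modulation(A, reg, k = 4)
    tt <- im$table[im$table$state == 1, ]
    all(tt$t > 0) && any(tt$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("dwell-performance Spearman correlations behave at the extremes", {
  set.seed(51)
  dwell <- matrix(runif(120, 1, 20), 60, 2)
  # monotone transform: rho = 1
  perf <- data.frame(rt = exp(dwell[, 1] / 10))
  res <- dwell_performance_correlation(dwell, perf)
  expect_equal(res$rho[res$state == 1], 1)
  # independent columns stay near zero
  perf2 <- data.frame(acc = rnorm(60))
  res2 <- dwell_performance_correlation(dwell, perf2)
  expect_lt(max(abs(res2$rho)), 0.35)
  # too few complete pairs: skipped with warning
  perf3 <- data.frame(err = c(rnorm(5), rep(NA, 55)))
  w <- capture_warnings(res3 <- dwell_performance_correlation(dwell, perf3))
  expect_length(w, 2)            # one skip per state
  expect_match(w, "complete pairs", all = TRUE)
  expect_true(all(is.na(res3$rho)))
})

test_that("a lapse state's dwell time predicts simulated too-late errors", {
  set.seed(61)
  n <- 120
  dwell <- matrix(runif(3 * n, 2, 12), n, 3)
  too_late <- rpois(n, lambda = 2 + dwell[, 3])
  res <- dwell_performance_correlation(dwell, data.frame(too_late = too_late))
  row <- res[res$state == 3, ]
  expect_gt(row$rho, 0.3)
  expect_true(row$significant)
})

test_that("the label-shuffle surrogate is anticonservative for sticky dynamics", {
  # autocorrelated occupancy makes exchangeable shuffling reject far above
  # the nominal level, which is why the calibration studies use the
  # circular-shift surrogate
  cal <- study_modulation_null(n_datasets = 10, n_perm = 200, seed = 42,
                               null_method = "shuffle")
  expect_gt(cal$rejection_rate, 0.15)
})
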