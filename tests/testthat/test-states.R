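test_that("exemplar selection finds strict local variance maxima", {
  # build wfnc stubs with prescribed per-window variance profiles
  stub <- function(v) {
    vals <- t(vapply(v, function(x) c(0, sqrt(x) * c(-1, 1)), numeric(3)))
    structure(list(values = vals, subject_id = "s"), class = "wfnc")
  }
  ex <- select_exemplars(list(stub(c(1, 3, 2, 5, 4))))
  expect_equal(ex$window, c(2, 4))
  expect_warning(ex2 <- select_exemplars(list(stub(1:5), stub(c(1, 9, 1)))),
                 "no local variance maxima")
  expect_equal(ex2$subject, 2)
  # plateau takes its first index
  ex3 <- select_exemplars(list(stub(c(1, 4, 4, 1, 2))))
  expect_equal(ex3$window, 2)
})

test_that("two-stage k-means recovers well-separated planted clusters", {
  wl <- blob_wfnc(k = 2, seed = 3)
  m <- fit_states(wl, 2, n_replicates = 20, seed = 1)
  expect_gte(matched_accuracy(m, wl), 0.95)

  # k = 1: centroid is the grand mean
  m1 <- fit_states(wl, 1, seed = 1)
  X <- do.call(rbind, lapply(wl, `[[`, "values"))
  expect_equal(m1$centroids[1, ], colMeans(X))

  # duplicating the dataset leaves assignments identical
  m2 <- fit_states(c(wl, wl), 2, n_replicates = 20, seed = 1)
  expect_equal(unname(unlist(m2$assignments[seq_along(wl)])),
               unname(unlist(m2$assignments[seq_along(wl) + length(wl)])))
})

test_that("the elbow criterion finds four well-separated planted states", {
  hits <- vapply(1:5, function(s) {
    wl <- blob_wfnc(k = 4, seed = s, sep = 3)
    elbow_curve(wl, 2:7, n_replicates = 10, seed = s)$chosen_k == 4
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # identical repeated points per cluster: CVI = 0 at the true k
  set.seed(2)
  cents <- matrix(rnorm(3 * 30, sd = 4), 3, 30)
  wl0 <- lapply(1:6, function(i) {
    lab <- sample(rep(1:3, length.out = 40))
    structure(list(values = cents[lab, ], subject_id = paste0("r", i)),
              class = "wfnc")
  })
  ec <- elbow_curve(wl0, 2:5, n_replicates = 10, seed = 1)
  expect_lt(ec$cvi[2], 1e-10)
})

test_that("occurrence and dwell metrics obey their normalizations", {
  A <- rbind(c(1, 1, 2), c(1, 2, 2), c(2, 2, 1))
  occ <- group_occurrence(A, k = 2)
  expect_equal(occ[, 1], c(state1 = 2 / 3, state2 = 1 / 3))
  expect_equal(colSums(occ), rep(1, 3))

  d <- dwell_and_fraction(rbind(c(1, 1, 2, 2, 2, 1)), k = 2, tr_seconds = 2.2)
  expect_equal(unname(d$dwell[1, ]), c(1.5, 3))
  expect_equal(unname(d$fraction[1, ]), c(0.5, 0.5))
  expect_equal(unname(d$dwell_seconds[1, ]), c(1.5, 3) * 2.2)

  d2 <- dwell_and_fraction(rbind(c(2, 2, 2)), k = 3)
  expect_equal(unname(d2$dwell[1, ]), c(NA, 3, NA))
  expect_equal(unname(d2$fraction[1, ]), c(0, 1, 0))
  expect_equal(unname(rowSums(d2$fraction)), 1)
})

test_that("mean dwell matches the chain's geometric sojourn law", {
  cfg <- synthetic_config(n_states = 2, n_components = 4, n_timepoints = 400,
    state_covariances = make_block_covariances(4, 2), task_coupling = 0,
    base_transition = matrix(c(0.8, 0.2, 0.2, 0.8), 2), seed = 3)
  set.seed(3)
  dw <- t(vapply(1:100, function(i)
    sequence_dwell(dynstates:::sample_state_chain(cfg), 2)$dwell, numeric(2)))
  # geometric sojourn mean 1/(1 - p_stay) = 5
  se <- apply(dw, 2, sd) / sqrt(100)
  expect_true(all(abs(colMeans(dw) - 5) < 3 * se + 0.2))
})

test_that("relabelling states permutes all metrics consistently", {
  A <- matrix(sample(1:3, 60, replace = TRUE), 4, 15)
  perm <- c(3, 1, 2)
  Ap <- matrix(perm[A], 4, 15)
  occ <- group_occurrence(A, k = 3)
  occp <- group_occurrence(Ap, k = 3)
  expect_equal(unname(occp[perm, ]), unname(occ))
  d <- dwell_and_fraction(A, k = 3)
  dp <- dwell_and_fraction(Ap, k = 3)
  expect_equal(unname(dp$dwell[, perm]), unname(d$dwell))
  expect_equal(unname(dp$fraction[, perm]), unname(d$fraction))
})

test_that("cross-session centroid similarity reproduces the matched-state design", {
  set.seed(8)
  base <- matrix(rnorm(4 * 50), 4, 50)
  sessions <- lapply(1:4, function(s) base[sample(4), ] +
                       matrix(rnorm(200, sd = 0.15), 4, 50))
  res <- centroid_similarity_test(sessions)
  expect_equal(res$n_same, 24)
  expect_equal(res$n_diff, 96)
  expect_equal(res$df, 118)
  expect_gt(res$mean_same, res$mean_diff)

  # identical centroids across sessions: within-group r is exactly 1
  res2 <- centroid_similarity_test(list(base, base, base))
  expect_equal(unname(res2$r_same), rep(1, 12))

  expect_error(centroid_similarity_test(list(base)), "at least 2")
  expect_error(centroid_similarity_test(list(base, base[1:3, ])), "differs")
})

test_that("the summary-statistics t reproduces the printed similarity contrast", {
  # group summaries as printed for matched FNC states (r 0.86 +/- 0.17 in
  # the same state, 0.67 +/- 0.10 across states; 24 and 96 pairs): the
  # recomputed two-sample t on the rounded inputs is 7.12 with df 118
  # (unrounded data print as 7.17)
  st <- t_from_summary(0.86, 0.17, 24, 0.67, 0.10, 96)
  expect_equal(st$df, 118)
  expect_equal(st$t, 7.117, tolerance = 1e-3)
  expect_lt(st$p, 1e-9)
  expect_gt(st$cohens_d, 1.5)
})
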