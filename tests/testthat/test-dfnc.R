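test_that("pair_count and the canonical pair order are stable", {
  expect_identical(pair_count(61), 1830L)
  expect_identical(pair_count(2), 1L)
  expect_identical(pair_count(10), 45L)
  expect_error(pair_count(1), "at least 2")

  idx <- pair_index(4)
  expect_equal(idx[, "i"], c(1, 1, 1, 2, 2, 3))
  expect_equal(idx[, "j"], c(2, 3, 4, 3, 4, 4))

  M <- matrix(rnorm(25), 5); M <- (M + t(M)) / 2; diag(M) <- 1
  expect_equal(fnc_mat(fnc_vec(M)), M)
})

test_that("taper matches a direct convolution oracle and its limits", {
  tp <- build_taper(8, 3)
  # independent double-loop discrete convolution of rectangle and kernel
  half <- ceiling(4 * 3)
  kern <- exp(-(-half:half)^2 / (2 * 9)); kern <- kern / sum(kern)
  full <- vapply(seq_len(8 + 2 * half), function(k)
    sum(vapply(1:8, function(i) {
      j <- k - i + 1
      if (j >= 1 && j <= length(kern)) kern[j] else 0
    }, numeric(1))), numeric(1))
  oracle <- full[(half + 1):(half + 8)]
  oracle <- oracle / max(oracle)
  expect_lt(max(abs(tp$weights - oracle)), 1e-12)

  # symmetry and unimodality
  expect_lt(max(abs(tp$weights - rev(tp$weights))), 1e-12)
  expect_lt(tp$weights[1], tp$weights[4])
  expect_equal(tp$weights[4], tp$weights[5])

  # delta-kernel limit: pure rectangle
  expect_equal(build_taper(8, 1e-3)$weights, rep(1, 8))
})

test_that("windowed covariance equals the brute-force weighted oracle", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  tp <- build_taper(8, 3)
  S <- windowed_covariance(X, tp, 5)
  p <- tp$weights / sum(tp$weights)
  Xw <- X[5:12, ]
  mu <- colSums(Xw * p)
  oracle <- matrix(0, 3, 3)
  for (i in 1:8)
    oracle <- oracle + p[i] * outer(Xw[i, ] - mu, Xw[i, ] - mu)
  expect_lt(max(abs(S - oracle)), 1e-12)

  # anti-correlated pair under uniform weights
  y <- rnorm(8)
  Su <- windowed_covariance(cbind(y, -y), rep(1, 8), 1)
  expect_equal(cov2cor(Su)[1, 2], -1)

  # identical rows: zero covariance, flagged
  Sd <- windowed_covariance(matrix(1, 8, 2), tp, 1)
  expect_equal(max(abs(Sd)), 0)
  expect_equal(attr(Sd, "zero_variance"), 1:2)
})

test_that("graphical lasso limits and KKT optimality hold", {
  set.seed(7)
  X <- matrix(rnorm(300 * 5), 300, 5) %*% matrix(rnorm(25), 5)
  S <- cov(X)
  # full shrinkage
  expect_equal(max(abs(glasso_correlation(S, 10))), 0)
  # unpenalized identity
  expect_lt(max(abs(glasso_correlation(S, 0) - fnc_vec(cov2cor(S)))), 1e-6)
  # KKT conditions of the penalized problem (independent optimality check)
  rho <- 0.1
  fit <- glasso_fit(S, rho, tol = 1e-6)
  R <- cov2cor(S)
  W <- solve(fit$theta)
  D <- W - R
  expect_lt(max(abs(diag(D) - rho)), 1e-6)
  off <- upper.tri(D)
  nz <- off & fit$theta != 0
  z0 <- off & fit$theta == 0
  if (any(nz)) expect_lt(max(abs(D[nz] - rho * sign(fit$theta[nz]))), 1e-6)
  if (any(z0)) expect_lte(max(abs(D[z0])), rho + 1e-6)
})

test_that("windowed FNC has W = T - w rows that are valid correlation profiles", {
  set.seed(11)
  ts <- component_ts(matrix(rnorm(200 * 5), 200, 5))
  wf <- compute_windowed_fnc(ts, w = 8, lambda = 0.1)
  expect_equal(nrow(wf$values), 192)
  expect_true(all(abs(wf$values) <= 1))
  M <- fnc_mat(wf$values[10, ])
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 5))
  expect_error(compute_windowed_fnc(matrix(rnorm(10), 5, 2), w = 8), "too short")
})

test_that("single-state windowed FNC time-averages to the static FNC", {
  cfg <- synthetic_config(n_states = 1, n_components = 6, n_timepoints = 300,
    state_covariances = make_block_covariances(6, 1, 0.6, -0.3, 2))
  sub <- simulate_subject(cfg, NULL, 5)
  wf <- compute_windowed_fnc(sub$ts, w = 8, lambda = 0)
  st <- compute_static_fnc(sub$ts)
  expect_lt(max(abs(colMeans(wf$values) - st$values)), 0.1)
})

test_that("static FNC handles exact and degenerate cases", {
  y <- rnorm(30)
  st <- compute_static_fnc(cbind(a = y, b = 2 * y + 1))
  expect_equal(st$values, 1)
  st2 <- compute_static_fnc(cbind(y, -y))
  expect_equal(st2$values, -1)
  set.seed(1)
  long <- matrix(rnorm(4000), 2000, 2)
  expect_lt(abs(compute_static_fnc(long)$values), 3 / sqrt(2000))
  expect_error(compute_static_fnc(cbind(y, rep(1, 30))), "zero-variance component")
})

test_that("state centroids are robust to the window length", {
  # default generative conditions at a 30-subject scale
  cfg <- synthetic_config(n_subjects = 30, seed = 77)
  des <- block_design(total_s = cfg$n_timepoints * cfg$tr_seconds)
  coh <- simulate_cohort(cfg, des, seed = 77)
  wf8 <- lapply(coh$subjects, function(s) compute_windowed_fnc(s$ts, 8, 3, 0.1))
  wf4 <- lapply(coh$subjects, function(s) compute_windowed_fnc(s$ts, 4, 3, 0.1))
  m8 <- fit_states(wf8, 4, n_replicates = 20, seed = 1)
  m4 <- fit_states(wf4, 4, n_replicates = 20, seed = 1)
  perm <- match_states(m8$centroids, m4$centroids)
  expect_gt(min(attr(perm, "r")), 0.8)
})
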