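test_that("signed Louvain attains the exhaustive-partition optimum on small nets", {
  # two disconnected positive cliques: partition recovers the cliques
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- 0.5; W[4:6, 4:6] <- 0.5; diag(W) <- 0
  fit <- signed_louvain(W, seed = 1)
  expect_equal(fit$partition, c(1, 1, 1, 2, 2, 2))
  expect_equal(fit$q, brute_force_best_q(W), tolerance = 1e-12)

  # random signed networks up to 7 nodes: Louvain equals brute force
  set.seed(11)
  for (trial in 1:6) {
    n <- sample(5:7, 1)
    M <- matrix(rnorm(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
    f <- signed_louvain(M, seed = trial)
    expect_equal(f$q, brute_force_best_q(M), tolerance = 1e-9)
  }

  # uniform positive complete graph has no community structure
  U <- matrix(0.4, 5, 5); diag(U) <- 0
  fu <- signed_louvain(U, seed = 1)
  expect_equal(length(unique(fu$partition)), 1L)
  expect_lt(abs(fu$q), 1e-12)

  # all-zero network: single module, Q = 0
  f0 <- signed_louvain(matrix(0, 4, 4))
  expect_equal(f0$q, 0)
  expect_equal(f0$partition, rep(1L, 4))
})

test_that("Q of the returned partition is at least the one-module Q", {
  set.seed(21)
  for (trial in 1:5) {
    M <- matrix(rnorm(64), 8); M <- (M + t(M)) / 2; diag(M) <- 0
    f <- signed_louvain(M, seed = trial)
    expect_gte(f$q, signed_modularity(M, rep(1L, 8)) - 1e-12)
  }
})

test_that("participation coefficients match closed forms and a brute-force oracle", {
  # all links inside the node's own module
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1
  pc <- participation_coefficients(W, c(1, 1, 2, 2))
  expect_equal(pc$node_pos[1], 0)
  # equal strength to each of 3 modules: 1 - 1/3
  W2 <- matrix(0, 4, 4)
  W2[1, 2:4] <- W2[2:4, 1] <- 1
  pc2 <- participation_coefficients(W2, c(1, 1, 2, 3))
  expect_equal(pc2$node_pos[1], 1 - 3 * (1 / 3)^2)
  # random network vs double-loop oracle, both sign layers
  set.seed(5)
  M <- matrix(rnorm(100), 10); M <- (M + t(M)) / 2; diag(M) <- 0
  part <- sample(1:3, 10, replace = TRUE)
  pc3 <- participation_coefficients(M, part)
  expect_lt(max(abs(pc3$node_pos - brute_force_pc(M, part, "pos"))), 1e-12)
  expect_lt(max(abs(pc3$node_neg - brute_force_pc(M, part, "neg"))), 1e-12)
  expect_true(all(pc3$node_pos >= 0 & pc3$node_pos <= 1))
})

test_that("signed randomization conserves sign-layer degree sequences", {
  set.seed(13)
  M <- matrix(rnorm(14 * 14), 14); M <- (M + t(M)) / 2; diag(M) <- 0
  M[abs(M) < 0.6] <- 0   # sparsify so rewiring has room
  R <- randomize_signed(M, seed = 2)
  expect_equal(R, t(R))
  bin_deg <- function(A) list(pos = rowSums(A > 0), neg = rowSums(A < 0))
  expect_equal(bin_deg(R), bin_deg(M))
  expect_equal(sort(R[R > 0]), sort(M[M > 0]))
  expect_equal(sort(R[R < 0]), sort(M[M < 0]))
  # all-positive network: randomizations have no negative layer
  P <- abs(M)
  Rp <- randomize_signed(P, seed = 3)
  expect_true(all(Rp >= 0))
  expect_equal(participation_coefficients(Rp,
    signed_louvain(Rp, seed = 1)$partition)$neg, 0)
})

test_that("randomized networks of a modular graph have lower modularity", {
  set.seed(17)
  W <- matrix(-0.15, 12, 12)
  W[1:6, 1:6] <- 0.6; W[7:12, 7:12] <- 0.6
  W <- W + matrix(rnorm(144, sd = 0.05), 12); W <- (W + t(W)) / 2; diag(W) <- 0
  gm <- graph_metrics(W, n_rand = 30, seed = 1, n_runs = 8)
  expect_gt(gm$q, mean(gm$rand[, "q"]))
  expect_gt(gm$q_norm, 1)
})

test_that("across-state ANOVA has the matched-session degrees of freedom", {
  # 4 states x 4 sessions: F(3, 12)
  set.seed(19)
  tab <- matrix(rnorm(16), 4, 4) + c(0, 0, 0, 3)
  res <- compare_states(tab)
  expect_equal(res$df, c(3, 12))
  expect_gt(res$eta_squared, 0.5)
  # the shifted state drives significant post-hoc contrasts
  sig_pairs <- res$posthoc[res$posthoc$significant, c("state_a", "state_b")]
  expect_true(all(sig_pairs == 4 | sig_pairs < 4))

  # identical metric across states: F = 0, no rejections
  tab0 <- matrix(rep(rnorm(4), each = 4), 4, 4)
  res0 <- compare_states(tab0)
  expect_equal(res0$f, 0)
  expect_false(any(res0$posthoc$significant))
  expect_error(compare_states(matrix(1, 4, 1)), "at least 2")
})

test_that("a planted mean shift is detected by the post-hoc contrasts", {
  # with S = 4 sessions per state a 4-SD shift is detected reliably
  # (measured power at a 3-SD shift is only about 0.76 at this tiny n)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    tab <- matrix(rnorm(16), 4, 4)
    tab[2, ] <- tab[2, ] + 4
    res <- compare_states(tab)
    ph <- res$posthoc
    all(ph$significant[ph$state_a == 2 | ph$state_b == 2])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
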