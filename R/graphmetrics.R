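#' Signed network from a centroid profile
#'
#' Rebuilds the symmetric weight matrix from a vectorized FNC profile and
#' zeroes the diagonal.
#'
#' @param x P-vector (canonical pair order) or symmetric C x C matrix.
#' @return symmetric C x C matrix with zero diagonal.
#' @export
signed_network <- function(x) {
  W <- if (is.matrix(x)) x else fnc_mat(x, diag_value = 0)
  if (max(abs(W - t(W))) > 1e-12) stopf("network must be symmetric")
  diag(W) <- 0
  W
}

# modularity matrix for the asymmetric signed quality
# Q = Q+ - (s-/(s+ + s-)) Q-, where Q+- are the Newman modularities of the
# positive / negative layers normalized by their own total weight. With
# B = (W+ - k+ k+'/s+)/s+ - (W- - k- k-'/s-)/(s+ + s-), Q = sum_in-module B.
signed_modularity_matrix <- function(W) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp_ <- sum(Wp); sn_ <- sum(Wn)
  B <- matrix(0, nrow(W), ncol(W))
  if (sp_ > 0) {
    kp <- rowSums(Wp)
    B <- B + (Wp - outer(kp, kp) / sp_) / sp_
  }
  if (sn_ > 0) {
    kn <- rowSums(Wn)
    B <- B - (Wn - outer(kn, kn) / sn_) / (sp_ + sn_)
  }
  B
}

#' Signed modularity of a given partition
#'
#' Asymmetric signed quality: the positive layer's Newman modularity minus
#' the negative layer's, the latter down-weighted by s- / (s+ + s-), the
#' convention for functional brain networks.
#'
#' @param W symmetric signed weight matrix (zero diagonal).
#' @param partition integer module labels.
#' @return scalar Q.
#' @export
signed_modularity <- function(W, partition) {
  B <- signed_modularity_matrix(W)
  same <- outer(partition, partition, "==")
  sum(B[same])
}

# one greedy Louvain pass on a modularity matrix; ord is the node order and
# init an optional starting partition (default singletons). Moves include
# detaching a node into a fresh singleton community.
louvain_matrix <- function(B, ord, init = NULL) {
  n <- nrow(B)
  node_comm <- seq_len(n)          # community of each original node
  level_B <- B
  level_init <- init
  repeat {
    m <- nrow(level_B)
    comm <- if (!is.null(level_init)) match(level_init, unique(level_init))
            else seq_len(m)
    level_init <- NULL             # random init applies to the first level only
    improved <- FALSE
    repeat {
      moved <- FALSE
      for (i in if (m == n) ord else seq_len(m)) {
        ci <- comm[i]
        # modularity-matrix weight from i to each community (self excluded);
        # a fresh singleton community has weight 0
        w_to <- tapply(level_B[i, -i], comm[-i], sum)
        base <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
        gains <- c(w_to, 0) - base
        cand <- c(as.integer(names(w_to)), max(comm) + 1L)
        bi <- which.max(gains)
        if (gains[[bi]] > 1e-12 && cand[bi] != ci) {
          comm[i] <- cand[bi]
          moved <- TRUE
          improved <- TRUE
        }
      }
      if (!moved) break
    }
    comm <- match(comm, unique(comm))
    node_comm <- comm[node_comm]
    if (!improved || length(unique(comm)) == nrow(level_B)) break
    # aggregate
    agg <- rowsum(t(rowsum(level_B, comm)), comm)
    level_B <- as.matrix(agg)
    if (nrow(level_B) == 1) break
  }
  node_comm
}

#' Signed Louvain community detection
#'
#' Greedy Louvain optimization of the asymmetric signed modularity, best of
#' `n_runs` seeded node-order restarts. Networks of at most 10 nodes get at
#' least 200 restarts: each restart is then nearly free, and greedy local
#' optima on tiny dense signed networks occasionally need many reorderings
#' to escape. The all-zero network returns a single module with Q = 0.
#'
#' @param W symmetric signed weight matrix (or P-vector).
#' @param seed integer seed for the restart node orders.
#' @param n_runs number of restarts (default 20).
#' @return list: `partition` (integer labels), `q` (modularity of the best
#'   partition).
#' @export
signed_louvain <- function(W, seed = 1L, n_runs = 20) {
  W <- signed_network(W)
  n <- nrow(W)
  if (all(W == 0))
    return(list(partition = rep(1L, n), q = 0))
  if (n <= 10) n_runs <- max(n_runs, 200)
  B <- signed_modularity_matrix(W)
  set.seed(as.integer(seed))
  best_part <- rep(1L, n)
  best_q <- signed_modularity(W, best_part)
  for (r in seq_len(n_runs)) {
    # alternate singleton starts with random initial partitions, which
    # reach basins the singleton-start greedy cannot
    init <- if (r %% 2 == 0)
      sample.int(sample.int(min(n, 5), 1), n, replace = TRUE) else NULL
    part <- louvain_matrix(B, sample.int(n), init)
    q <- signed_modularity(W, part)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_part <- part
    }
  }
  list(partition = match(best_part, unique(best_part)), q = best_q)
}

#' Sign-stratified participation coefficients
#'
#' For each sign layer, node PC_i = 1 - sum_m (s_im / s_i)^2 over modules m,
#' with strengths restricted to that sign's absolute weights; nodes with no
#' strength in a layer contribute 0. Returns node-averaged values.
#'
#' @param W symmetric signed weight matrix (or P-vector).
#' @param partition integer module labels covering all nodes.
#' @return list: `pos`, `neg` (node means), `node_pos`, `node_neg`.
#' @export
participation_coefficients <- function(W, partition) {
  W <- signed_network(W)
  if (length(partition) != nrow(W)) stopf("partition must cover all nodes")
  pc_layer <- function(A) {
    s <- rowSums(A)
    sm <- rowsum(t(A), partition)            # modules x nodes
    frac2 <- rowSums((t(sm) / ifelse(s == 0, 1, s))^2)
    ifelse(s == 0, 0, 1 - frac2)
  }
  node_pos <- pc_layer(pmax(W, 0))
  node_neg <- pc_layer(pmax(-W, 0))
  list(pos = mean(node_pos), neg = mean(node_neg),
       node_pos = node_pos, node_neg = node_neg)
}

#' Degree-preserving randomization of a signed network
#'
#' Within each sign layer: degree-preserving edge swaps (10 attempts per
#' edge, rejecting swaps that collide with existing edges of either layer,
#' so the layers stay disjoint), followed by a random permutation of that
#' layer's weight multiset over its rewired edges. Both sign layers keep
#' their exact degree sequences and edge counts. On dense matrices few
#' swaps are admissible and the null is dominated by the weight
#' permutation.
#'
#' @param W symmetric signed weight matrix (or P-vector).
#' @param seed integer seed.
#' @param swaps_per_edge rewiring attempts per edge (default 10).
#' @return randomized symmetric matrix.
#' @export
randomize_signed <- function(W, seed = 1L, swaps_per_edge = 10) {
  W <- signed_network(W)
  set.seed(as.integer(seed))
  n <- nrow(W)
  idx <- pair_index(n)
  vals <- W[idx]
  pos <- which(vals > 0); neg <- which(vals < 0)
  edges <- list(pos = idx[pos, , drop = FALSE], neg = idx[neg, , drop = FALSE])
  weights <- list(pos = vals[pos], neg = vals[neg])
  occupied <- matrix(FALSE, n, n)
  for (cl in c("pos", "neg")) {
    E <- edges[[cl]]
    if (nrow(E)) occupied[E] <- occupied[E[, c(2, 1), drop = FALSE]] <- TRUE
  }
  for (cl in c("pos", "neg")) {
    E <- edges[[cl]]
    ne <- nrow(E)
    if (ne >= 2) {
      for (a in seq_len(swaps_per_edge * ne)) {
        ij <- sample.int(ne, 2)
        e1 <- E[ij[1], ]; e2 <- E[ij[2], ]
        # propose (i1, j2), (i2, j1)
        n1 <- sort(c(e1[1], e2[2])); n2 <- sort(c(e2[1], e1[2]))
        if (n1[1] == n1[2] || n2[1] == n2[2]) next
        if (occupied[n1[1], n1[2]] || occupied[n2[1], n2[2]]) next
        if (all(n1 == sort(e1)) || all(n1 == sort(e2))) next
        occupied[e1[1], e1[2]] <- occupied[e1[2], e1[1]] <- FALSE
        occupied[e2[1], e2[2]] <- occupied[e2[2], e2[1]] <- FALSE
        occupied[n1[1], n1[2]] <- occupied[n1[2], n1[1]] <- TRUE
        occupied[n2[1], n2[2]] <- occupied[n2[2], n2[1]] <- TRUE
        E[ij[1], ] <- n1; E[ij[2], ] <- n2
      }
      edges[[cl]] <- E
    }
    weights[[cl]] <- sample(weights[[cl]])
  }
  R <- matrix(0, n, n)
  for (cl in c("pos", "neg")) {
    E <- edges[[cl]]
    if (nrow(E)) {
      R[E] <- weights[[cl]]
      R[E[, c(2, 1), drop = FALSE]] <- weights[[cl]]
    }
  }
  R
}

#' Graph metrics of one FNC state, normalized against randomized networks
#'
#' Computes signed-Louvain modularity and sign-stratified participation
#' coefficients, then divides each by its mean over `n_rand` randomized
#' networks (degree-preserving within sign layers).
#'
#' @param net centroid P-vector or symmetric matrix.
#' @param n_rand number of randomized networks (default 100).
#' @param seed integer seed.
#' @param n_runs Louvain restarts per network (default 20).
#' @return list: `partition`, `q`, `p_pos`, `p_neg`, `q_norm`, `p_pos_norm`,
#'   `p_neg_norm`, `rand` (matrix of null metrics).
#' @export
graph_metrics <- function(net, n_rand = 100, seed = 1L, n_runs = 20) {
  W <- signed_network(net)
  fit <- signed_louvain(W, seed = seed, n_runs = n_runs)
  pc <- participation_coefficients(W, fit$partition)
  rand <- matrix(NA_real_, n_rand, 3,
                 dimnames = list(NULL, c("q", "p_pos", "p_neg")))
  for (r in seq_len(n_rand)) {
    Wr <- randomize_signed(W, seed = seed + r)
    fr <- signed_louvain(Wr, seed = seed + r, n_runs = max(2, n_runs %/% 4))
    pr <- participation_coefficients(Wr, fr$partition)
    rand[r, ] <- c(fr$q, pr$pos, pr$neg)
  }
  mu <- colMeans(rand)
  list(partition = fit$partition, q = fit$q, p_pos = pc$pos, p_neg = pc$neg,
       q_norm = fit$q / mu["q"],
       p_pos_norm = pc$pos / mu["p_pos"],
       p_neg_norm = pc$neg / mu["p_neg"],
       rand = rand)
}

#' Across-state comparison of a graph metric
#'
#' One-way ANOVA of a metric across states with sessions as observations
#' (k = 4 states over S = 4 sessions gives F with (3, 12) degrees of
#' freedom), eta-squared effect size, and BH-FDR-corrected pairwise
#' two-sample t-tests.
#'
#' @param metric_table k x S numeric matrix (states x sessions).
#' @param q FDR level for the post-hoc tests (default 0.05).
#' @return list: `f`, `df`, `p`, `eta_squared`, `posthoc` (data.frame with
#'   state pair, t, p, q-value, significant).
#' @export
compare_states <- function(metric_table, q = 0.05) {
  metric_table <- as.matrix(metric_table)
  k <- nrow(metric_table); S <- ncol(metric_table)
  if (S < 2) stopf("need at least 2 sessions per state")
  df <- data.frame(value = as.vector(metric_table),
                   state = factor(rep(seq_len(k), S)))
  fit <- lm(value ~ state, data = df)
  av <- anova(fit)
  ss_state <- av[["Sum Sq"]][1]
  ss_tot <- sum(av[["Sum Sq"]])
  pairs <- utils::combn(k, 2)
  ph <- data.frame(state_a = pairs[1, ], state_b = pairs[2, ],
                   t = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    tt <- t.test(metric_table[pairs[1, j], ], metric_table[pairs[2, j], ],
                 var.equal = TRUE)
    ph$t[j] <- unname(tt$statistic)
    ph$p[j] <- tt$p.value
  }
  ph$q_value <- p.adjust(ph$p, "BH")
  ph$significant <- ph$q_value < q
  list(f = av[["F value"]][1],
       df = c(av[["Df"]][1], av[["Df"]][2]),
       p = av[["Pr(>F)"]][1],
       eta_squared = ss_state / ss_tot,
       posthoc = ph)
}
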