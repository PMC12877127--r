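# windowed-FNC objects drawn directly from k well-separated Gaussian
# clusters (no time-series estimation), for clustering-only tests
blob_wfnc <- function(n_subjects = 6, windows_per_subject = 40, k = 4,
                      p = 30, sep = 3, seed = 1) {
  set.seed(seed)
  centres <- matrix(rnorm(k * p, sd = sep), k, p)
  lapply(seq_len(n_subjects), function(i) {
    lab <- sort(rep_len(seq_len(k), windows_per_subject))
    vals <- centres[lab, ] + matrix(rnorm(windows_per_subject * p, sd = 0.3),
                                    windows_per_subject, p)
    structure(list(values = vals, window_start_tr = seq_len(windows_per_subject),
                   window_centre_tr = seq_len(windows_per_subject) + 3,
                   w = 8L, sigma = 3, lambda = 0, tr_seconds = 2.2,
                   subject_id = sprintf("b%02d", i), session = "blob",
                   truth = lab),
              class = "wfnc")
  })
}

# exhaustive-partition oracle for the asymmetric signed modularity,
# written straight from the Q+ / Q- definitions (independent of the
# package's modularity-matrix formulation)
brute_force_best_q <- function(W) {
  n <- nrow(W)
  all_partitions <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in all_partitions(n - 1))
      for (g in seq_len(max(p) + 1))
        out[[length(out) + 1]] <- c(p, g)
    out
  }
  q_of <- function(part) {
    Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
    sp <- sum(Wp); sn <- sum(Wn)
    d <- outer(part, part, "==")
    qp <- if (sp > 0) {
      kp <- rowSums(Wp); sum(((Wp - outer(kp, kp) / sp) / sp)[d])
    } else 0
    qn <- if (sn > 0) {
      kn <- rowSums(Wn); sum(((Wn - outer(kn, kn) / sn) / sn)[d])
    } else 0
    qp - if (sp + sn > 0) sn / (sp + sn) * qn else 0
  }
  max(vapply(all_partitions(n), q_of, numeric(1)))
}

# brute-force participation coefficient, double loop over nodes/modules
brute_force_pc <- function(W, partition, sign_class = "pos") {
  A <- if (sign_class == "pos") pmax(W, 0) else pmax(-W, 0)
  vapply(seq_len(nrow(A)), function(i) {
    s <- sum(A[i, ])
    if (s == 0) return(0)
    1 - sum(vapply(unique(partition), function(m)
      (sum(A[i, partition == m]) / s)^2, numeric(1)))
  }, numeric(1))
}

# map fitted labels onto planted labels by best centroid match and return
# the fraction of windows agreeing with the planted cluster identity
matched_accuracy <- function(model, wfnc_list) {
  truth_lab <- unlist(lapply(wfnc_list, `[[`, "truth"))
  est_lab <- unlist(model$assignments, use.names = FALSE)
  k <- model$k
  perms <- build_permutations(k)
  best <- 0
  for (p in perms) best <- max(best, mean(p[est_lab] == truth_lab))
  best
}

build_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in build_permutations(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}
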