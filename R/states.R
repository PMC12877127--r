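#' Subject exemplar windows
#'
#' For each subject, computes the variance of each window's FNC profile
#' across component pairs and keeps the windows at strict local maxima of
#' that variance over time (interior points only; for a flat local maximum
#' the first index of the plateau is taken). These high-variance windows
#' seed the group clustering, analogous to EEG microstate peak selection.
#'
#' @param wfnc_list list of `wfnc` objects (one per subject).
#' @return list: `exemplars` (matrix of exemplar FNC profiles), `subject`
#'   (subject index per exemplar), `window` (window index per exemplar),
#'   `n_per_subject`.
#' @export
select_exemplars <- function(wfnc_list) {
  ex <- list(); subj <- integer(); win <- integer()
  for (i in seq_along(wfnc_list)) {
    V <- wfnc_list[[i]]$values
    if (nrow(V) < 3) stopf("subject %d has fewer than 3 windows", i)
    v <- row_vars(V)
    idx <- local_maxima(v)
    if (!length(idx)) {
      warnf("subject %d has no local variance maxima; contributes no exemplars", i)
      next
    }
    ex[[length(ex) + 1]] <- V[idx, , drop = FALSE]
    subj <- c(subj, rep(i, length(idx)))
    win <- c(win, idx)
  }
  if (!length(ex)) stopf("no exemplars found in any subject")
  n_per <- tabulate(subj, nbins = length(wfnc_list))
  list(exemplars = do.call(rbind, ex), subject = subj, window = win,
       n_per_subject = n_per)
}

# strict interior local maxima; plateaus contribute their first index
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  if (m < 3) return(integer())
  keep <- which(vapply(seq_len(m), function(i) {
    i > 1 && i < m && r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]
  }, logical(1)))
  starts[keep]
}

# one k-means run under the chosen metric; correlation metric = euclidean
# k-means on row-standardized profiles
kmeans_run <- function(X, init, metric, max_iter = 100) {
  mcode <- switch(metric, euclidean = 0L, cityblock = 1L, correlation = 0L,
                  stopf("unknown metric '%s'", metric))
  kmeans_core(X, init, mcode, as.integer(max_iter))
}

standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- sqrt(row_vars(X))
  sdv[sdv == 0] <- 1
  (X - mu) / sdv
}

#' Fit FNC states by two-stage k-means
#'
#' Stage 1 clusters the subject exemplars with `n_replicates` random
#' restarts and keeps the lowest-inertia solution; stage 2 runs a single
#' k-means pass over all windows initialized at the stage-1 centroids.
#' Default distance is cityblock (L1, median centroid update), the
#' convention of the reference dFNC pipeline; `euclidean` and `correlation`
#' (euclidean on row-standardized profiles) are also available. Empty
#' clusters are re-seeded at the farthest point.
#'
#' @param wfnc_list list of `wfnc` objects.
#' @param k number of states (>= 1).
#' @param n_replicates stage-1 restarts (default 150).
#' @param metric one of "cityblock", "euclidean", "correlation".
#' @param seed integer seed for the restarts.
#' @return object of class `state_model`: `k`, `centroids` (k x P),
#'   `assignments` (list of per-subject window label vectors),
#'   `assignment_matrix` (subjects x W when grids match, else NULL),
#'   `inertia`, `metric`, `exemplar_info`.
#' @export
fit_states <- function(wfnc_list, k, n_replicates = 150,
                       metric = "cityblock", seed = 1L) {
  if (k < 1) stopf("k must be >= 1")
  X <- do.call(rbind, lapply(wfnc_list, function(w) w$values))
  nw <- vapply(wfnc_list, function(w) nrow(w$values), integer(1))
  Xfit <- if (metric == "correlation") standardize_rows(X) else X
  if (k == 1) {
    cent <- matrix(colMeans(Xfit), 1)
    assign_all <- rep(1L, nrow(X))
    inertia <- NA_real_
    ex <- NULL
  } else {
    ex <- select_exemplars(wfnc_list)
    Ex <- ex$exemplars
    if (metric == "correlation") Ex <- standardize_rows(Ex)
    if (nrow(Ex) < k) stopf("fewer exemplars (%d) than clusters (%d)",
                            nrow(Ex), k)
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(n_replicates)) {
      init <- Ex[sample.int(nrow(Ex), k), , drop = FALSE]
      fit <- kmeans_run(Ex, init, metric)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    final <- kmeans_run(Xfit, best$centroids, metric)
    cent <- final$centroids
    assign_all <- final$assignment + 1L
    inertia <- final$inertia
  }
  assignments <- split(assign_all, rep(seq_along(nw), nw))
  names(assignments) <- vapply(wfnc_list, function(w)
    w$subject_id %||% "s", character(1))
  amat <- if (length(unique(nw)) == 1)
    do.call(rbind, assignments) else NULL
  structure(list(k = as.integer(k), centroids = cent,
                 assignments = assignments, assignment_matrix = amat,
                 inertia = inertia, metric = metric,
                 n_replicates = n_replicates,
                 exemplar_info = ex),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d (%s metric), %d subjects, inertia %.4g\n",
              x$k, x$metric, length(x$assignments), x$inertia))
  invisible(x)
}

#' Cluster-validity elbow curve
#'
#' CVI(k) = mean within-cluster distance to centroid divided by mean
#' between-centroid distance, computed under the fitted metric. The chosen
#' k maximizes the second-order forward difference of the curve (maximum
#' curvature); a `weak_elbow` flag is raised when the maximal curvature is
#' below 10 percent of the CVI range.
#'
#' @param wfnc_list list of `wfnc` objects.
#' @param k_range candidate cluster numbers, a subset of 2..9.
#' @param n_replicates stage-1 restarts per k (default 30 here; the curve is
#'   a model-selection diagnostic, not the final fit).
#' @param metric clustering distance.
#' @param seed integer seed.
#' @return list: `k_range`, `cvi`, `chosen_k`, `weak_elbow`, `models`.
#' @export
elbow_curve <- function(wfnc_list, k_range = 2:9, n_replicates = 30,
                        metric = "cityblock", seed = 1L) {
  if (min(k_range) < 2 || max(k_range) > 9)
    stopf("k_range must lie within [2, 9]")
  n_windows <- sum(vapply(wfnc_list, function(w) nrow(w$values), integer(1)))
  if (n_windows <= max(k_range)) stopf("fewer windows than clusters")
  models <- lapply(k_range, function(k)
    fit_states(wfnc_list, k, n_replicates = n_replicates, metric = metric,
               seed = seed))
  X <- do.call(rbind, lapply(wfnc_list, function(w) w$values))
  if (metric == "correlation") X <- standardize_rows(X)
  cvi <- vapply(models, function(m) {
    a <- unlist(m$assignments, use.names = FALSE)
    within <- mean(vapply(seq_len(nrow(X)), function(i)
      row_dist(X[i, ], m$centroids[a[i], ], metric), numeric(1)))
    cc <- m$centroids
    pairs <- utils::combn(nrow(cc), 2)
    between <- mean(vapply(seq_len(ncol(pairs)), function(j)
      row_dist(cc[pairs[1, j], ], cc[pairs[2, j], ], metric), numeric(1)))
    if (between == 0) Inf else within / between
  }, numeric(1))
  ks <- as.integer(k_range)
  chosen <- NA_integer_; weak <- TRUE
  if (length(ks) >= 3) {
    d2 <- cvi[seq_len(length(ks) - 2)] - 2 * cvi[seq_len(length(ks) - 2) + 1] +
      cvi[seq_len(length(ks) - 2) + 2]
    chosen <- ks[which.max(d2) + 1]
    rng <- diff(range(cvi))
    weak <- rng == 0 || max(d2) < 0.1 * rng
  }
  list(k_range = ks, cvi = cvi, chosen_k = chosen, weak_elbow = weak,
       models = models)
}

row_dist <- function(x, y, metric) {
  switch(metric,
         cityblock = sum(abs(x - y)),
         euclidean = sum((x - y)^2),
         correlation = sum((x - y)^2))
}

#' Group-level state occurrence
#'
#' Proportion of subjects occupying each state at each window. Requires all
#' subjects to share the window grid.
#'
#' @param model a `state_model` (or an integer subjects x W assignment
#'   matrix).
#' @param k number of states (taken from the model when given).
#' @return k x W matrix of proportions; columns sum to 1.
#' @export
group_occurrence <- function(model, k = NULL) {
  if (inherits(model, "state_model")) {
    A <- model$assignment_matrix
    if (is.null(A))
      stopf("subjects have ragged window grids; compute per-subject occurrence instead")
    k <- model$k
  } else {
    A <- as.matrix(model)
    if (is.null(k)) k <- max(A)
  }
  occ <- t(vapply(seq_len(k), function(s) colMeans(A == s),
                  numeric(ncol(A))))
  rownames(occ) <- paste0("state", seq_len(k))
  occ
}

#' Dwell times and fraction times
#'
#' Dwell time is the mean length of maximal consecutive runs of a state in
#' a subject's window sequence (NA when never visited); fraction time is
#' the share of windows spent in the state. Dwell is reported in windows,
#' with seconds alongside when the TR is known.
#'
#' @param model a `state_model`, or a list/matrix of label sequences.
#' @param k number of states.
#' @param tr_seconds TR for the seconds-scale dwell (optional).
#' @return list: `dwell` (subjects x k, windows), `dwell_seconds`,
#'   `fraction` (subjects x k, rows sum to 1).
#' @export
dwell_and_fraction <- function(model, k = NULL, tr_seconds = NULL) {
  if (inherits(model, "state_model")) {
    seqs <- model$assignments
    k <- model$k
  } else if (is.matrix(model)) {
    seqs <- split(model, row(model))
    if (is.null(k)) k <- max(model)
  } else {
    seqs <- model
    if (is.null(k)) k <- max(unlist(seqs))
  }
  res <- lapply(seqs, sequence_dwell, k = k)
  dwell <- do.call(rbind, lapply(res, `[[`, "dwell"))
  fraction <- do.call(rbind, lapply(res, `[[`, "fraction"))
  colnames(dwell) <- colnames(fraction) <- paste0("state", seq_len(k))
  list(dwell = dwell,
       dwell_seconds = if (!is.null(tr_seconds)) dwell * tr_seconds else NULL,
       fraction = fraction)
}

#' Match state labels across sessions
#'
#' Greedy best-match on centroid Pearson correlation against a reference
#' centroid set; ties broken by lower state index.
#'
#' @param reference k x P centroid matrix.
#' @param target k x P centroid matrix to relabel.
#' @return integer permutation `perm` such that `target[perm[s], ]` matches
#'   `reference[s, ]`, with the matched correlations as attribute `r`.
#' @export
match_states <- function(reference, target) {
  k <- nrow(reference)
  R <- suppressWarnings(cor(t(reference), t(target)))
  if (any(!is.finite(R))) {
    # cosine fallback for constant profiles, where Pearson is undefined
    nr <- sqrt(rowSums(reference^2)); nt <- sqrt(rowSums(target^2))
    Cs <- (reference %*% t(target)) / outer(pmax(nr, 1e-12), pmax(nt, 1e-12))
    R[!is.finite(R)] <- Cs[!is.finite(R)]
  }
  perm <- integer(k); rs <- numeric(k)
  free_r <- seq_len(k); free_t <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- R[free_r, free_t, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    perm[free_r[best[1]]] <- free_t[best[2]]
    rs[free_r[best[1]]] <- sub[best[1], best[2]]
    free_r <- free_r[-best[1]]; free_t <- free_t[-best[2]]
  }
  attr(perm, "r") <- rs
  perm
}

#' Cross-session centroid similarity test
#'
#' After greedy state matching, correlates every pair of (state, session)
#' centroids and compares same-state cross-session correlations (n1 =
#' k S(S-1)/2) against different-state correlations (n2 = C(kS, 2) - n1)
#' with a two-sample pooled t-test (df = n1 + n2 - 2) and Cohen's d. With
#' k = 4 states and S = 4 sessions this is the t with 118 degrees of
#' freedom reported for matched FNC states.
#'
#' @param session_models list of `state_model`s (or k x P centroid
#'   matrices), one per session; k must match.
#' @return list with group means/SDs, `t`, `df`, `p`, `cohens_d`, `conf_int`,
#'   `n_same`, `n_diff`, and the full correlation table.
#' @export
centroid_similarity_test <- function(session_models) {
  cents <- lapply(session_models, function(m)
    if (inherits(m, "state_model")) m$centroids else as.matrix(m))
  S <- length(cents)
  if (S < 2) stopf("need at least 2 sessions")
  ks <- vapply(cents, nrow, integer(1))
  if (length(unique(ks)) != 1) stopf("state count differs across sessions")
  k <- ks[1]
  for (s in 2:S) cents[[s]] <- cents[[s]][match_states(cents[[1]], cents[[s]]), ,
                                          drop = FALSE]
  flat <- do.call(rbind, cents)                  # (k*S) x P, state-major in rows
  state_of <- rep(seq_len(k), S)
  R <- cor(t(flat))
  pr <- which(upper.tri(R), arr.ind = TRUE)
  same <- state_of[pr[, 1]] == state_of[pr[, 2]]
  r_same <- R[pr[same, , drop = FALSE]]
  r_diff <- R[pr[!same, , drop = FALSE]]
  st <- t_from_summary(mean(r_same), sd(r_same), length(r_same),
                       mean(r_diff), sd(r_diff), length(r_diff))
  c(list(mean_same = mean(r_same), sd_same = sd(r_same),
         mean_diff = mean(r_diff), sd_diff = sd(r_diff),
         n_same = length(r_same), n_diff = length(r_diff),
         r_same = r_same, r_diff = r_diff), st)
}

#' Two-sample pooled t from summary statistics
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list: `t`, `df`, `p` (two-sided), `cohens_d`, `conf_int` (95
#'   percent CI of the mean difference).
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  tval <- (m1 - m2) / se
  ci <- (m1 - m2) + c(-1, 1) * qt(0.975, df) * se
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
       cohens_d = (m1 - m2) / sp, conf_int = ci)
}
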