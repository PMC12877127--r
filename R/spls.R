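# soft threshold
soft <- function(a, d) {
  z <- abs(a) - d
  z[z < 0] <- 0
  sign(a) * z
}

# scale a to unit L2 norm after soft-thresholding with the smallest delta
# such that ||u||_1 <= c; c in [1, sqrt(length(a))]. On the segment where m
# coordinates stay active the L1/L2 ratio of soft(a, delta) is an analytic
# function of delta, so the threshold solves a quadratic per segment.
l1_unit <- function(a, c1) {
  if (all(a == 0)) return(a)
  u <- a / sqrt(sum(a^2))
  if (sum(abs(u)) <= c1) return(u)
  s <- sort(abs(a), decreasing = TRUE)
  p <- length(s)
  ratio <- function(d) {
    v <- s[s > d] - d
    if (!length(v)) return(0)
    sum(v) / sqrt(sum(v^2))
  }
  # bracket the segment [knots m+1, m] where the ratio crosses c1
  delta <- s[1]
  for (m in seq_len(p)) {
    lo_d <- if (m < p) s[m + 1] else 0
    if (ratio(lo_d) < c1) next
    S1 <- sum(s[seq_len(m)]); S2 <- sum(s[seq_len(m)]^2)
    A <- m * (m - c1^2)
    Bq <- -2 * S1 * (m - c1^2)
    Cq <- S1^2 - c1^2 * S2
    if (abs(A) < 1e-12 && abs(Bq) < 1e-12 && abs(Cq) < 1e-12) {
      # ratio equals c1 throughout this segment (e.g. c1 = 1 with a single
      # active coordinate); the smallest admissible threshold is the lower
      # knot, which zeroes the next coordinate exactly
      delta <- lo_d
      break
    }
    cand <- if (abs(A) < 1e-14) {
      if (abs(Bq) < 1e-14) numeric() else -Cq / Bq
    } else {
      disc <- Bq^2 - 4 * A * Cq
      if (disc < 0) numeric()
      else (-Bq + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    cand <- cand[cand >= lo_d - 1e-10 & cand <= s[m] + 1e-10]
    if (length(cand)) {
      # squaring the ratio equation can introduce spurious roots; accept
      # only a root that actually attains the target ratio (ties can make
      # the constraint infeasible, in which case the zero vector results)
      hit <- abs(vapply(cand, ratio, numeric(1)) - c1) < 1e-6 * max(1, c1)
      if (any(hit)) {
        cand <- cand[hit]
        delta <- max(min(cand[1], s[m]), lo_d)
        break
      }
    }
  }
  u <- soft(a, delta)
  nrm <- sqrt(sum(u^2))
  if (nrm == 0) a * 0 else u / nrm
}

#' One-component sparse PLS
#'
#' Alternating soft-thresholded power iteration on the cross-covariance
#' X'Y, with L1 constraints `c_x`, `c_y` on the unit-norm weight vectors
#' (c = sqrt(p) is the unconstrained limit, recovering the leading singular
#' vectors). Converges when the weight change is below `tol`.
#'
#' @param X n x p matrix (e.g. state dwell times), columns centred.
#' @param Y n x q matrix (e.g. behaviours), columns centred.
#' @param c_x,c_y L1 constraints in [1, sqrt(p)], [1, sqrt(q)].
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter maximum iterations (default 200).
#' @return list: `u`, `v` (unit-norm sparse weights), `cor` (latent-score
#'   correlation on the fitting data), `iterations`, `converged`.
#' @export
spls_fit <- function(X, Y, c_x, c_y, tol = 1e-6, max_iter = 200) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  M <- crossprod(X, Y)
  sv <- svd(M, nu = 1, nv = 1)
  v <- sv$v[, 1]
  u <- sv$u[, 1]
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    u_new <- l1_unit(as.numeric(M %*% v), c_x)
    if (all(u_new == 0)) return(list(u = u_new, v = v, cor = NA_real_,
                                     iterations = it, converged = FALSE))
    v_new <- l1_unit(as.numeric(crossprod(M, u_new)), c_y)
    if (all(v_new == 0)) return(list(u = u_new, v = v_new, cor = NA_real_,
                                     iterations = it, converged = FALSE))
    if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new; converged <- TRUE
      break
    }
    u <- u_new; v <- v_new
  }
  lx <- as.numeric(X %*% u); ly <- as.numeric(Y %*% v)
  r <- if (sd(lx) == 0 || sd(ly) == 0) NA_real_ else cor(lx, ly)
  list(u = u, v = v, cor = r, iterations = it, converged = converged)
}

latent_cor <- function(X, Y, u, v) {
  lx <- as.numeric(as.matrix(X) %*% u)
  ly <- as.numeric(as.matrix(Y) %*% v)
  if (sd(lx) == 0 || sd(ly) == 0) return(NA_real_)
  cor(lx, ly)
}

#' Multiple-holdout sparse PLS association
#'
#' For each of `n_splits` seeded 80/20 train/test splits: the training set
#' is further split 80/20 into an inner training and validation set; a grid
#' of L1 constraints (log-spaced between 1 and sqrt(dim), `grid_size` per
#' view) is searched for the pair maximizing the validation latent-score
#' correlation; the model refit on the full training set is evaluated on
#' the held-out test set, with significance from `n_perm` permutations of
#' the training-Y rows (refit, test-set latent correlation null). The split
#' with the highest test-set association is reported, alongside all splits.
#' Per-split permutation p-values are exchangeable-valid; the best-split
#' selection is a reporting convention and is optimistic.
#'
#' @param X n x p matrix (deconfounded dwell times).
#' @param Y n x q matrix (deconfounded behaviours).
#' @param n_splits outer random splits (default 3).
#' @param n_perm permutations per split (default 5000).
#' @param grid_size L1 grid points per view (default 5).
#' @param seed integer seed.
#' @return list: `best` (the reported split: u, v, test_cor, p, c_x, c_y),
#'   `splits` (per-split summaries), `n_perm`.
#' @export
spls_multiple_holdout <- function(X, Y, n_splits = 3, n_perm = 5000,
                                  grid_size = 5, seed = 1L) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  n <- nrow(X)
  if (n < 50) stopf("need n >= 50 subjects, got %d", n)
  grid_x <- exp(seq(log(1), log(sqrt(ncol(X))), length.out = grid_size))
  grid_y <- exp(seq(log(1), log(sqrt(ncol(Y))), length.out = grid_size))
  set.seed(as.integer(seed))
  splits <- vector("list", n_splits)
  for (sp in seq_len(n_splits)) {
    test_idx <- sample.int(n, round(0.2 * n))
    train_idx <- setdiff(seq_len(n), test_idx)
    val_idx <- sample(train_idx, round(0.2 * length(train_idx)))
    inner_idx <- setdiff(train_idx, val_idx)
    ctr <- function(M, idx) scale(M[idx, , drop = FALSE], scale = FALSE)
    best_val <- -Inf; best_cx <- grid_x[grid_size]; best_cy <- grid_y[grid_size]
    for (cx in grid_x) for (cy in grid_y) {
      f <- spls_fit(ctr(X, inner_idx), ctr(Y, inner_idx), cx, cy)
      if (all(f$u == 0) || all(f$v == 0)) next
      vc <- latent_cor(ctr(X, val_idx), ctr(Y, val_idx), f$u, f$v)
      if (!is.na(vc) && abs(vc) > best_val) {
        best_val <- abs(vc); best_cx <- cx; best_cy <- cy
      }
    }
    Xtr <- ctr(X, train_idx); Ytr <- ctr(Y, train_idx)
    Xte <- ctr(X, test_idx);  Yte <- ctr(Y, test_idx)
    fit <- spls_fit(Xtr, Ytr, best_cx, best_cy)
    obs <- latent_cor(Xte, Yte, fit$u, fit$v)
    null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      Yp <- Ytr[sample.int(nrow(Ytr)), , drop = FALSE]
      fp <- spls_fit(Xtr, Yp, best_cx, best_cy)
      null[b] <- if (all(fp$u == 0) || all(fp$v == 0)) 0
                 else latent_cor(Xte, Yte, fp$u, fp$v)
    }
    p <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
    splits[[sp]] <- list(u = fit$u, v = fit$v, test_cor = obs, p = p,
                         c_x = best_cx, c_y = best_cy,
                         validation_cor = best_val)
  }
  test_cors <- vapply(splits, function(s) abs(s$test_cor %||% NA_real_),
                      numeric(1))
  best <- splits[[which.max(test_cors)]]
  list(best = best, splits = splits, n_perm = n_perm)
}
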