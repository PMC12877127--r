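#' Number of component pairs
#'
#' Count of unordered component pairs, the length of every vectorized FNC
#' profile. For the 61 components of a typical high-model-order ICA this is
#' 1830.
#'
#' @param C number of components (>= 2).
#' @return integer, C(C-1)/2.
#' @export
pair_count <- function(C) {
  if (C < 2) stopf("need at least 2 components, got %d", C)
  as.integer(C * (C - 1) / 2)
}

#' Upper-triangle pair indices in the package's canonical order
#'
#' Row-major upper triangle: (1,2), (1,3), ..., (1,C), (2,3), ... This order
#' is shared by every module that vectorizes or reconstructs FNC matrices.
#'
#' @param C number of components.
#' @return integer matrix with columns `i`, `j` (i < j), one row per pair.
#' @export
pair_index <- function(C) {
  p <- which(upper.tri(diag(C)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' Vectorize a symmetric matrix / rebuild it from a vector
#'
#' `fnc_vec` extracts the upper triangle in the canonical pair order;
#' `fnc_mat` inverts it, placing `diag_value` on the diagonal.
#'
#' @param M symmetric C x C matrix.
#' @param v length-P vector, P = C(C-1)/2.
#' @param diag_value diagonal fill for the reconstruction (default 1).
#' @return `fnc_vec`: numeric P-vector; `fnc_mat`: symmetric C x C matrix.
#' @export
fnc_vec <- function(M) {
  M[pair_index(nrow(M))]
}

#' @rdname fnc_vec
#' @export
fnc_mat <- function(v, diag_value = 1) {
  P <- length(v)
  C <- (1 + sqrt(1 + 8 * P)) / 2
  if (abs(C - round(C)) > 1e-8) stopf("length %d is not a pair count", P)
  C <- as.integer(round(C))
  M <- diag(diag_value, C)
  idx <- pair_index(C)
  M[idx] <- v
  M[idx[, c(2, 1)]] <- v
  M
}

#' Tapered sliding window
#'
#' The taper is a length-w rectangle convolved with a unit-area Gaussian
#' kernel (support truncated at +/- 4 sigma), cropped to the central w
#' samples and renormalized so the maximum weight is 1. With sigma -> 0 it
#' degenerates to the plain rectangle.
#'
#' @param w window length in TRs (>= 2).
#' @param sigma Gaussian kernel width in TRs (default 3).
#' @return object of class `taper` with fields `w`, `sigma`, `weights`.
#' @export
build_taper <- function(w, sigma = 3) {
  if (w < 2) stopf("window length must be >= 2")
  if (sigma <= 0) stopf("sigma must be positive")
  half <- max(1L, ceiling(4 * sigma))
  tk <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  tk <- tk / sum(tk)
  rect <- rep(1, w)
  full <- convolve(rect, rev(tk), type = "open")   # length w + 2*half
  weights <- full[(half + 1):(half + w)]
  weights <- weights / max(weights)
  structure(list(w = as.integer(w), sigma = sigma, weights = weights),
            class = "taper")
}

#' Taper-weighted sample covariance of one window
#'
#' Weighted covariance with both the means and the cross-products weighted
#' by the normalized taper.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param taper a [build_taper()] object (or numeric weight vector).
#' @param start_tr 1-based TR index of the first sample in the window.
#' @return C x C symmetric covariance matrix; attribute `zero_variance`
#'   lists components constant within the window.
#' @export
windowed_covariance <- function(ts, taper, start_tr = 1) {
  X <- as_cts(ts)$values
  wts <- if (inherits(taper, "taper")) taper$weights else as.numeric(taper)
  w <- length(wts)
  if (start_tr + w - 1 > nrow(X))
    stopf("window [%d, %d] exceeds %d timepoints", start_tr, start_tr + w - 1,
          nrow(X))
  p <- wts / sum(wts)
  Xw <- X[start_tr:(start_tr + w - 1), , drop = FALSE]
  mu <- colSums(Xw * p)
  Xc <- sweep(Xw, 2, mu)
  S <- crossprod(Xc, Xc * p)
  S <- (S + t(S)) / 2
  zv <- which(diag(S) <= 1e-14)
  if (length(zv)) attr(S, "zero_variance") <- zv
  S
}

#' Graphical lasso on a window covariance
#'
#' Estimates a sparse precision matrix by L1-penalized maximum likelihood
#' on the correlation-scaled covariance (block coordinate descent), then
#' returns the correlation form of its inverse. `lambda = 0` is the
#' unpenalized case and returns the input correlation unchanged.
#'
#' @param cov symmetric C x C covariance.
#' @param lambda L1 penalty on off-diagonal precision entries (>= 0).
#' @param tol convergence tolerance (default 1e-4).
#' @param max_iter maximum outer sweeps (default 500).
#' @return list: `correlation` (P-vector in canonical order), `theta`
#'   (sparse precision on the correlation scale), `w` (estimated
#'   covariance), `lambda`.
#' @export
glasso_fit <- function(cov, lambda, tol = 1e-4, max_iter = 500) {
  if (lambda < 0) stopf("lambda must be non-negative")
  if (max(abs(cov - t(cov))) > 1e-8) stopf("covariance must be symmetric")
  d <- diag(cov)
  if (any(d <= 0)) stopf("zero-variance component: %s",
                         paste(which(d <= 0), collapse = ", "))
  R <- cov2cor(cov)
  if (lambda == 0) {
    # unpenalized case: the correlation is the estimate itself; the precision
    # is only reported when the window is non-singular
    th <- tryCatch(solve(R), error = function(e) NULL)
    return(list(correlation = fnc_vec(R), theta = th, w = R, lambda = 0))
  }
  fit <- glasso_cpp(R, lambda, tol, as.integer(max_iter))
  if (!fit$converged) {
    fit <- glasso_cpp(R, 2 * lambda, tol, as.integer(max_iter))
    if (!fit$converged)
      stopf("graphical lasso failed to converge at lambda = %g and %g",
            lambda, 2 * lambda)
    lambda <- 2 * lambda
  }
  W <- cov2cor(fit$w)
  list(correlation = fnc_vec(W), theta = fit$theta, w = W, lambda = lambda)
}

#' @rdname glasso_fit
#' @export
glasso_correlation <- function(cov, lambda, tol = 1e-4, max_iter = 500) {
  glasso_fit(cov, lambda, tol = tol, max_iter = max_iter)$correlation
}

#' Tapered sliding-window FNC estimation
#'
#' Slides a tapered window forward `stride` TRs at a time (default 1, so the
#' number of windows is W = T - w), estimating one regularized whole-brain
#' FNC profile per window.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param w window length in TRs; 8 TR (17.6 s at TR 2.2 s) for block
#'   designs, 4 TR for short-block designs.
#' @param sigma taper Gaussian width in TRs (default 3).
#' @param lambda graphical-lasso penalty (default 0.1; 0 = plain weighted
#'   correlation).
#' @param stride window step in TRs (default 1).
#' @param fisher_z apply Fisher z-transform to the vectorized profiles
#'   (default FALSE).
#' @return object of class `wfnc`: `values` (W x P matrix), `window_start_tr`,
#'   `window_centre_tr`, `w`, `sigma`, `lambda`, `tr_seconds`, `subject_id`.
#' @export
compute_windowed_fnc <- function(ts, w = 8, sigma = 3, lambda = 0.1,
                                 stride = 1, fisher_z = FALSE) {
  ts <- as_cts(ts)
  T_ <- nrow(ts$values)
  C <- ncol(ts$values)
  if (T_ <= w) stopf("T = %d too short for window length %d", T_, w)
  taper <- build_taper(w, sigma)
  starts <- seq.int(1L, T_ - w, by = stride)
  P <- pair_count(C)
  vals <- matrix(NA_real_, length(starts), P)
  for (jj in seq_along(starts)) {
    S <- windowed_covariance(ts, taper, starts[jj])
    vals[jj, ] <- glasso_fit(S, lambda)$correlation
  }
  if (fisher_z) vals <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
  structure(list(values = vals,
                 window_start_tr = starts,
                 window_centre_tr = starts + (w - 1) %/% 2,
                 w = as.integer(w), sigma = sigma, lambda = lambda,
                 fisher_z = fisher_z,
                 tr_seconds = ts$tr_seconds,
                 subject_id = ts$subject_id, session = ts$session),
            class = "wfnc")
}

#' @export
print.wfnc <- function(x, ...) {
  cat(sprintf("<wfnc> subject %s: %d windows x %d pairs (w = %d TR, lambda = %g)\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$w, x$lambda))
  invisible(x)
}

#' Static (full-session) FNC
#'
#' Pearson correlation of each component pair over the entire session,
#' vectorized in the canonical pair order.
#'
#' @param ts component time-series (`cts` or matrix).
#' @return object of class `sfnc` with `values` (P-vector) and `subject_id`.
#' @export
compute_static_fnc <- function(ts) {
  ts <- as_cts(ts)
  X <- ts$values
  if (nrow(X) < 3) stopf("need at least 3 timepoints")
  sds <- col_sds(X)
  if (any(sds == 0))
    stopf("zero-variance component: %s", paste(which(sds == 0), collapse = ", "))
  structure(list(values = fnc_vec(cor(X)), subject_id = ts$subject_id),
            class = "sfnc")
}
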