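#' Polynomial detrending
#'
#' Removes, per component, the least-squares fit of polynomials in the time
#' index up to `max_degree` (constant through cubic by default), the first
#' step of component time-course post-processing.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param max_degree highest polynomial degree removed (default 3).
#' @return detrended series of the same class and shape.
#' @export
polynomial_detrend <- function(ts, max_degree = 3) {
  if (max_degree < 1) stopf("max_degree must be >= 1")
  cts_map(ts, function(X) {
    T_ <- nrow(X)
    if (T_ <= max_degree + 1) stopf("insufficient timepoints for degree %d",
                                    max_degree)
    tt <- seq_len(T_) / T_
    basis <- outer(tt, 0:max_degree, "^")
    qr.resid(qr(basis), X)
  })
}

#' Nuisance regression
#'
#' Per-component OLS residualization on the supplied regressors (motion
#' parameters and, for task sessions, the HRF-convolved task design)
#' augmented with an intercept. Rank-deficient designs are handled by the
#' pivoted QR in `lm.fit`.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param regressors T x q numeric matrix (default: the series' own motion
#'   parameters).
#' @return residualized series.
#' @export
regress_nuisance <- function(ts, regressors = NULL) {
  ts <- as_cts(ts)
  if (is.null(regressors)) regressors <- ts$motion
  if (is.null(regressors)) stopf("no regressors supplied and no motion stored")
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(ts$values))
    stopf("regressors have %d rows, time-series has %d", nrow(regressors),
          nrow(ts$values))
  X <- cbind(1, regressors)
  cts_map(ts, function(Y) {
    fit <- lm.fit(X, Y)
    as.matrix(fit$residuals)
  })
}

#' Despiking by running-median outlier interpolation
#'
#' Flags samples whose deviation from a 5-TR running median exceeds
#' `z_thresh` robust SDs (1.4826 x MAD of the component's values)
#' and replaces them by linear interpolation between the nearest non-outlier
#' neighbours; endpoints clamp to the nearest valid value.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param z_thresh outlier threshold in robust SDs (default 3.5).
#' @return despiked series; attribute `n_despiked` counts replacements per
#'   component.
#' @export
despike <- function(ts, z_thresh = 3.5) {
  if (z_thresh <= 0) stopf("z_thresh must be positive")
  counts <- NULL
  out <- cts_map(ts, function(X) {
    T_ <- nrow(X)
    counts <<- integer(ncol(X))
    for (j in seq_len(ncol(X))) {
      y <- X[, j]
      med <- stats::runmed(y, k = min(5L, T_ - (1 - T_ %% 2)), endrule = "median")
      d <- y - med
      # robust scale of the column itself: the deviation MAD degenerates to
      # zero on smooth signals, where most samples equal their running median
      scale <- mad(y)
      if (scale == 0) next
      bad <- abs(d) > z_thresh * scale
      if (!any(bad)) next
      if (all(bad)) stopf("degenerate column %d: every sample flagged", j)
      good <- which(!bad)
      y[bad] <- approx(good, y[good], xout = which(bad), rule = 2)$y
      counts[j] <<- sum(bad)
      X[, j] <- y
    }
    X
  })
  attr(out, "n_despiked") <- counts
  out
}

#' Zero-phase low-pass filter
#'
#' 5th-order Butterworth applied forward and backward (zero phase), cutting
#' physiological and motor-response frequencies above the cutoff.
#'
#' @param ts component time-series (`cts` or matrix).
#' @param cutoff_hz cutoff frequency (default 0.18 Hz).
#' @param tr_seconds sampling interval, needed when `ts` is a bare matrix.
#' @return filtered series.
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.18, tr_seconds = NULL) {
  ts <- as_cts(ts)
  tr <- tr_seconds %||% ts$tr_seconds
  nyq <- 1 / (2 * tr)
  if (cutoff_hz >= nyq)
    stopf("cutoff %g Hz is at or above Nyquist %g Hz", cutoff_hz, nyq)
  bf <- signal::butter(5, cutoff_hz / nyq, type = "low")
  cts_map(ts, function(X) {
    n <- nrow(X)
    # odd-reflection padding suppresses the forward-backward edge transients
    L <- min(3 * 10, n - 1)
    apply(X, 2, function(y) {
      mu <- mean(y)
      yc <- y - mu
      head_pad <- 2 * yc[1] - rev(yc[2:(L + 1)])
      tail_pad <- 2 * yc[n] - rev(yc[(n - L):(n - 1)])
      yf <- signal::filtfilt(bf, c(head_pad, yc, tail_pad))
      yf[(L + 1):(L + n)] + mu
    })
  })
}

#' Full post-processing pipeline
#'
#' Fixed order: polynomial detrend, nuisance regression, despiking,
#' zero-phase low-pass.
#'
#' @param ts component time-series.
#' @param regressors nuisance design (default: stored motion parameters,
#'   plus `task_regressors` columns when given).
#' @param task_regressors optional T x q HRF-convolved task design to
#'   regress before windowing.
#' @param detrend_degree polynomial degree (default 3).
#' @param despike_z despiking threshold (default 3.5).
#' @param lowpass_hz low-pass cutoff (default 0.18).
#' @return post-processed `cts`.
#' @export
preprocess <- function(ts, regressors = NULL, task_regressors = NULL,
                       detrend_degree = 3, despike_z = 3.5,
                       lowpass_hz = 0.18) {
  ts <- as_cts(ts)
  reg <- regressors %||% ts$motion
  if (!is.null(task_regressors)) reg <- cbind(reg, as.matrix(task_regressors))
  out <- polynomial_detrend(ts, detrend_degree)
  if (!is.null(reg)) {
    # augment the design with the detrending basis so the nuisance
    # projection cannot reintroduce trend components (the two projections
    # then commute and the chain is idempotent up to filter edge effects)
    T_ <- nrow(out$values)
    basis <- outer(seq_len(T_) / T_, seq_len(detrend_degree), "^")
    out <- regress_nuisance(out, cbind(reg, basis))
  }
  out <- despike(out, despike_z)
  lowpass_filter(out, lowpass_hz)
}
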