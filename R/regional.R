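#' Per-subject pairwise FNC / condition correlations
#'
#' Correlation over windows between each component pair's FNC trajectory
#' and each condition's convolved regressor, for every subject. Constant
#' trajectories yield NA cells.
#'
#' @param wfnc_list list of `wfnc` objects.
#' @param regressors conditions x W matrix on the shared window grid.
#' @return subjects x P x conditions array.
#' @export
pair_condition_correlation <- function(wfnc_list, regressors) {
  n <- length(wfnc_list)
  P <- ncol(wfnc_list[[1]]$values)
  conds <- rownames(regressors) %||% paste0("cond", seq_len(nrow(regressors)))
  out <- array(NA_real_, c(n, P, length(conds)),
               dimnames = list(NULL, NULL, conds))
  for (i in seq_len(n)) {
    V <- wfnc_list[[i]]$values
    if (nrow(V) != ncol(regressors))
      stopf("subject %d has %d windows, regressors have %d", i, nrow(V),
            ncol(regressors))
    out[i, , ] <- suppressWarnings(cor(V, t(regressors)))
  }
  out
}

#' Condition-contrast t-statistics per pair
#'
#' One-sample t across subjects on the per-subject correlation difference
#' delta_r = r_a - r_b for each component pair, with BH-FDR over all P
#' pairs and top-k selection by |t| (ties broken by pair index).
#'
#' @param r_array subjects x P x conditions array from
#'   [pair_condition_correlation()].
#' @param condition_a,condition_b names of the contrasted conditions.
#' @param top_k number of selected pairs (default 20).
#' @param q FDR level (default 0.05).
#' @param signed select the top k by signed t (largest positive) instead of
#'   |t| (default FALSE).
#' @return object of class `regional_contrast`: `t_stats`, `p`, `q_value`,
#'   `significant`, `delta_r` (subjects x P), `top_k` (pair indices),
#'   `n_significant`, `contrast`.
#' @export
contrast_t <- function(r_array, condition_a, condition_b, top_k = 20,
                       q = 0.05, signed = FALSE) {
  D <- r_array[, , condition_a] - r_array[, , condition_b]
  n_ok <- colSums(!is.na(D))
  if (any(n_ok < 10)) stopf("fewer than 10 subjects with complete pairs")
  P <- ncol(D)
  if (top_k > P) stopf("top_k (%d) exceeds the number of pairs (%d)", top_k, P)
  mu <- colMeans(D, na.rm = TRUE)
  se <- apply(D, 2, sd, na.rm = TRUE) / sqrt(n_ok)
  tt <- mu / se
  tt[se == 0] <- 0
  p <- 2 * pt(-abs(tt), n_ok - 1)
  qv <- p.adjust(p, "BH")
  score <- if (signed) tt else abs(tt)
  sel <- order(-score, seq_len(P))[seq_len(top_k)]
  structure(list(t_stats = tt, p = p, q_value = qv,
                 significant = qv < q, n_significant = sum(qv < q),
                 delta_r = D, top_k = sel,
                 contrast = paste(condition_a, "-", condition_b)),
            class = "regional_contrast")
}

#' @export
print.regional_contrast <- function(x, ...) {
  cat(sprintf("<regional_contrast> %s: %d/%d pairs FDR-significant; top %d by |t|\n",
              x$contrast, x$n_significant, length(x$t_stats), length(x$top_k)))
  invisible(x)
}

#' Cross-task specificity of top regional FNC
#'
#' Takes the top-k pairs of one task's contrast and reports their
#' t-statistics, and the fraction FDR-significant, in the other tasks'
#' contrasts. A low fraction indicates task-specific modulation.
#'
#' @param contrast_a the reference `regional_contrast` (its `top_k` is used).
#' @param others named list of `regional_contrast`s from other tasks, on the
#'   same component space.
#' @return list: `table` (pair index with t in each contrast),
#'   `fraction_significant` (per other task).
#' @export
cross_task_specificity <- function(contrast_a, others) {
  P <- length(contrast_a$t_stats)
  for (o in others)
    if (length(o$t_stats) != P)
      stopf("component space mismatch between tasks")
  sel <- contrast_a$top_k
  tab <- data.frame(pair = sel, t_reference = contrast_a$t_stats[sel])
  frac <- numeric(0)
  for (nm in names(others)) {
    tab[[paste0("t_", nm)]] <- others[[nm]]$t_stats[sel]
    frac[nm] <- mean(others[[nm]]$significant[sel])
  }
  list(table = tab, fraction_significant = frac)
}
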