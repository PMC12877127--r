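#' Task design container
#'
#' Condition-labelled events with onsets and durations in seconds, the
#' BIDS-events convention. Conditions are enumerated in first-appearance
#' order.
#'
#' @param events data.frame with columns `onset`, `duration`, `trial_type`.
#' @return object of class `task_design` with `events` and `conditions`.
#' @export
task_design <- function(events) {
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("events table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(events$onset < 0)
  if (length(bad)) stopf("negative onset at row %d", bad[1])
  structure(list(events = events[need],
                 conditions = unique(as.character(events$trial_type))),
            class = "task_design")
}

#' Block design helper
#'
#' Alternating condition blocks separated by rest, the generic schedule of
#' blocked cognitive paradigms (emotional-faces or reward-anticipation
#' style).
#'
#' @param conditions condition labels cycled over blocks.
#' @param block_s block duration (s).
#' @param rest_s rest between blocks (s).
#' @param total_s total design duration (s).
#' @param start_s onset of the first block (s).
#' @return a [task_design()].
#' @export
block_design <- function(conditions = c("A", "B"), block_s = 22,
                         rest_s = 22, total_s = 440, start_s = 11) {
  onsets <- seq(start_s, total_s - block_s, by = block_s + rest_s)
  data <- data.frame(onset = onsets, duration = block_s,
                     trial_type = rep(conditions, length.out = length(onsets)))
  task_design(data)
}

#' Jittered event-related design helper
#'
#' Random event onsets per condition, a stop-signal-style event-related
#' schedule differing across subjects.
#'
#' @param conditions condition labels.
#' @param n_events events per condition.
#' @param duration_s event duration (s; 0 = impulse).
#' @param total_s design duration (s).
#' @param seed integer seed.
#' @return a [task_design()].
#' @export
event_design <- function(conditions = c("go", "stop"), n_events = 20,
                         duration_s = 1, total_s = 440, seed = 1L) {
  set.seed(as.integer(seed))
  ev <- do.call(rbind, lapply(conditions, function(cc)
    data.frame(onset = sort(runif(n_events, 0, total_s - duration_s - 1)),
               duration = duration_s, trial_type = cc)))
  task_design(ev[order(ev$onset), ])
}

#' Canonical double-gamma HRF kernel
#'
#' Response gamma peaking near 6 s minus an undershoot gamma at 16 s scaled
#' by 1/6, sampled at the TR and normalized to peak 1. The value at t = 0
#' is exactly 0.
#'
#' @param tr sampling interval (s).
#' @param length_s kernel support (default 32 s).
#' @return numeric kernel vector (first sample at t = 0).
#' @export
hrf_kernel <- function(tr, length_s = 32) {
  if (tr <= 0) stopf("tr must be positive")
  t <- seq(0, length_s, by = tr)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# condition boxcars convolved with the HRF, on the TR grid (cond x T).
# Zero-duration events are impulses at the TR containing the onset.
condition_regressors_tr <- function(design, tr, n_tr) {
  scan_end <- n_tr * tr
  h <- hrf_kernel(tr)
  reg <- matrix(0, length(design$conditions), n_tr,
                dimnames = list(design$conditions, NULL))
  tgrid <- (seq_len(n_tr) - 1) * tr
  for (cc in design$conditions) {
    ev <- design$events[design$events$trial_type == cc, , drop = FALSE]
    box <- numeric(n_tr)
    for (r in seq_len(nrow(ev))) {
      on <- ev$onset[r]; du <- ev$duration[r]
      if (on >= scan_end) {
        warnf("event at %gs beyond scan end (%gs); truncated", on, scan_end)
        next
      }
      if (du <= 0) {
        box[floor(on / tr) + 1] <- box[floor(on / tr) + 1] + 1
      } else {
        hit <- tgrid >= on & tgrid < min(on + du, scan_end)
        box[hit] <- 1
      }
    }
    conv <- convolve(box, rev(h), type = "open")[seq_len(n_tr)]
    reg[cc, ] <- conv
  }
  reg
}

#' HRF-convolved condition regressors on the window grid
#'
#' Builds a boxcar per condition at TR resolution, convolves it with the
#' canonical HRF, and samples the result at each window's centre TR
#' (centre = start + floor((w - 1) / 2)).
#'
#' @param design a [task_design()].
#' @param tr repetition time (s).
#' @param n_tr number of TRs in the session.
#' @param w window length in TRs.
#' @param stride window stride (default 1).
#' @return conditions x W regressor matrix (W = n_tr - w at stride 1).
#' @export
convolve_conditions <- function(design, tr, n_tr, w, stride = 1) {
  reg_tr <- condition_regressors_tr(design, tr, n_tr)
  starts <- seq.int(1L, n_tr - w, by = stride)
  centres <- starts + (w - 1) %/% 2
  reg_tr[, centres, drop = FALSE]
}

#' Group-level state-stimulus modulation with a permutation null
#'
#' Pearson correlation between each state's group occurrence time-course
#' and each condition regressor. The null rebuilds the group occurrence
#' from surrogate label sequences per subject and recomputes the
#' correlations; two-sided p = (1 + #(|r_null| >= |r_obs|)) / (n_perm + 1),
#' BH-FDR over states x conditions.
#'
#' Two surrogates are available. `"shuffle"` permutes each subject's
#' window labels (the literal label-shuffle null); it destroys the
#' temporal autocorrelation of state occupancy and is anticonservative
#' when dwell times span several windows. `"circular"` applies an
#' independent random circular shift per subject, preserving each
#' subject's run-length structure; it is the calibrated choice for
#' autocorrelated sequences.
#'
#' @param model a `state_model` (or subjects x W integer assignment matrix).
#' @param regressors conditions x W matrix from [convolve_conditions()].
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param q FDR level (default 0.05).
#' @param k number of states (taken from the model when given).
#' @param null_method `"shuffle"` (default) or `"circular"`.
#' @return list: `r` (k x conditions), `table` (tidy data.frame with r, p,
#'   q_value, significant), `null` (n_perm x (k * conditions) matrix).
#' @export
group_modulation <- function(model, regressors, n_perm = 5000, seed = 1L,
                             q = 0.05, k = NULL,
                             null_method = c("shuffle", "circular")) {
  null_method <- match.arg(null_method)
  if (inherits(model, "state_model")) {
    A <- model$assignment_matrix
    if (is.null(A)) stopf("ragged window grids; group modulation needs a shared grid")
    k <- model$k
  } else {
    A <- as.matrix(model)
    if (is.null(k)) k <- max(A)
  }
  W <- ncol(A)
  if (W < 10) stopf("need at least 10 windows")
  if (ncol(regressors) != W)
    stopf("regressors have %d columns, expected %d windows", ncol(regressors), W)
  n <- nrow(A)
  occ_cor <- function(M) {
    occ <- vapply(seq_len(k), function(s) colMeans(M == s), numeric(W))
    suppressWarnings(cor(occ, t(regressors)))   # k x cond; NA if constant
  }
  robs <- occ_cor(A)
  set.seed(as.integer(seed))
  null <- matrix(NA_real_, n_perm, length(robs))
  Ap <- A
  for (b in seq_len(n_perm)) {
    if (null_method == "shuffle") {
      for (i in seq_len(n)) Ap[i, ] <- A[i, sample.int(W)]
    } else {
      for (i in seq_len(n)) {
        sh <- sample.int(W, 1)
        Ap[i, ] <- A[i, ((seq_len(W) - 1 + sh) %% W) + 1]
      }
    }
    null[b, ] <- as.vector(occ_cor(Ap))
  }
  pvals <- vapply(seq_along(robs), function(j) {
    if (is.na(robs[j])) return(NA_real_)
    (1 + sum(abs(null[, j]) >= abs(robs[j]), na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  tab <- data.frame(state = rep(seq_len(k), times = ncol(robs)),
                    condition = rep(colnames(robs) %||%
                                      rownames(regressors), each = k),
                    r = as.vector(robs), p = pvals)
  ok <- !is.na(tab$p)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- p.adjust(tab$p[ok], "BH")
  tab$significant <- !is.na(tab$q_value) & tab$q_value < q
  dimnames(robs) <- list(paste0("state", seq_len(k)),
                         rownames(regressors))
  list(r = robs, table = tab, null = null)
}

#' Pearson-Filon z for two dependent correlations sharing one variable
#'
#' Compares r_ac and r_bc (both involving the shared variable c) given the
#' correlation r_ab between the two non-shared variables, on n samples.
#'
#' @param r_ac,r_bc the two correlations being compared.
#' @param r_ab correlation between variables a and b.
#' @param n sample size (> 4).
#' @return list: `z`, `p` (two-sided normal).
#' @export
pearson_filon_z <- function(r_ac, r_bc, r_ab, n) {
  if (n <= 4) stopf("n must exceed 4")
  if (any(abs(c(r_ac, r_bc, r_ab)) >= 1)) stopf("correlations must lie in (-1, 1)")
  khat <- r_ab * (1 - r_ac^2 - r_bc^2) -
    0.5 * r_ac * r_bc * (1 - r_ac^2 - r_bc^2 - r_ab^2)
  z <- (r_ac - r_bc) * sqrt(n) /
    sqrt((1 - r_ac^2)^2 + (1 - r_bc^2)^2 - 2 * khat)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# partial correlation of x and y given controls (residual method)
partial_cor <- function(x, y, controls = NULL) {
  if (is.null(controls) || (is.matrix(controls) && ncol(controls) == 0))
    return(suppressWarnings(cor(x, y)))
  Z <- cbind(1, as.matrix(controls))
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) return(NA_real_)
  cor(rx, ry)
}

#' Individual-level partial state-stimulus modulation
#'
#' For each subject and state, the partial correlation between the binary
#' state-occupancy indicator and each condition regressor, controlling for
#' the other conditions (residual method). Group inference is a one-sample
#' t-test of the per-subject coefficients against zero, BH-FDR over
#' states x conditions. Subjects with a constant indicator are excluded
#' from that state's test.
#'
#' @param model a `state_model` (or subjects x W assignment matrix).
#' @param regressors conditions x W matrix.
#' @param q FDR level (default 0.05).
#' @param k number of states.
#' @return list: `r` (subjects x states x conditions array), `table`
#'   (state, condition, mean_r, t, df, p, q_value, significant,
#'   n_excluded).
#' @export
individual_modulation <- function(model, regressors, q = 0.05, k = NULL) {
  if (inherits(model, "state_model")) {
    A <- model$assignment_matrix %||%
      do.call(rbind, model$assignments)
    k <- model$k
  } else {
    A <- as.matrix(model)
    if (is.null(k)) k <- max(A)
  }
  n <- nrow(A); W <- ncol(A)
  nc <- nrow(regressors)
  conds <- rownames(regressors) %||% paste0("cond", seq_len(nc))
  r <- array(NA_real_, c(n, k, nc), dimnames = list(NULL,
             paste0("state", seq_len(k)), conds))
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      ind <- as.numeric(A[i, ] == s)
      if (sd(ind) == 0) next
      for (cc in seq_len(nc)) {
        ctrl <- t(regressors[-cc, , drop = FALSE])
        r[i, s, cc] <- partial_cor(ind, regressors[cc, ], ctrl)
      }
    }
  }
  tab <- expand.grid(state = seq_len(k), condition = conds,
                     stringsAsFactors = FALSE)
  tab$mean_r <- NA_real_; tab$t <- NA_real_; tab$df <- NA_integer_
  tab$p <- NA_real_; tab$n_excluded <- NA_integer_
  for (j in seq_len(nrow(tab))) {
    vals <- r[, tab$state[j], tab$condition[j]]
    ok <- !is.na(vals)
    tab$n_excluded[j] <- sum(!ok)
    if (sum(ok) >= 3) {
      tt <- t.test(vals[ok])
      tab$mean_r[j] <- mean(vals[ok])
      tab$t[j] <- unname(tt$statistic)
      tab$df[j] <- unname(tt$parameter)
      tab$p[j] <- tt$p.value
    }
  }
  okp <- !is.na(tab$p)
  tab$q_value <- NA_real_
  tab$q_value[okp] <- p.adjust(tab$p[okp], "BH")
  tab$significant <- !is.na(tab$q_value) & tab$q_value < q
  list(r = r, table = tab)
}

#' Dwell-time / task-performance Spearman correlations
#'
#' Spearman's rank correlation between each state's dwell time and each
#' performance measure (rank-based because task performance is typically
#' non-normal), pairwise-complete, BH-FDR over all pairs. Pairs with fewer
#' than 10 complete observations are skipped with a warning.
#'
#' @param dwell subjects x k dwell-time matrix (NAs allowed).
#' @param performance subjects x m data.frame or matrix.
#' @param q FDR level (default 0.05).
#' @return data.frame: state, performance, rho, p, n, q_value, significant.
#' @export
dwell_performance_correlation <- function(dwell, performance, q = 0.05) {
  dwell <- as.matrix(dwell)
  performance <- as.data.frame(performance)
  out <- expand.grid(state = seq_len(ncol(dwell)),
                     performance = names(performance),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (j in seq_len(nrow(out))) {
    x <- dwell[, out$state[j]]
    y <- performance[[out$performance[j]]]
    ok <- complete.cases(x, y)
    out$n[j] <- sum(ok)
    if (sum(ok) < 10) {
      warnf("state %d vs %s: only %d complete pairs; skipped",
            out$state[j], out$performance[j], sum(ok))
      next
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    out$rho[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
  }
  ok <- !is.na(out$p)
  out$q_value <- NA_real_
  out$q_value[ok] <- p.adjust(out$p[ok], "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < q
  out
}
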