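#' Behaviour battery filtering
#'
#' Two multicollinearity/variance rules: iteratively drop the later (by
#' original column order) item of any pair with pairwise-complete |r| >
#' `r_max`; then drop near-zero-variance items whose modal value covers
#' more than `nzv_prop` of participants.
#'
#' @param raw data.frame or matrix of behavioural items.
#' @param r_max collinearity threshold (default 0.8).
#' @param nzv_prop modal-frequency threshold (default 0.95).
#' @return filtered data.frame; attribute `dropped` records items and
#'   reasons.
#' @export
filter_behaviours <- function(raw, r_max = 0.8, nzv_prop = 0.95) {
  tab <- as.data.frame(raw)
  if (ncol(tab) < 2) stopf("need at least 2 behavioural items")
  dropped <- data.frame(item = character(), reason = character())
  repeat {
    if (ncol(tab) < 2) break
    R <- suppressWarnings(cor(tab, use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    diag(R) <- 0
    hit <- which(abs(R) > r_max, arr.ind = TRUE)
    if (!nrow(hit)) break
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    drop_j <- hit[1, 2]
    dropped <- rbind(dropped, data.frame(item = names(tab)[drop_j],
      reason = sprintf("|r| = %.3f with %s", abs(R[hit[1, 1], drop_j]),
                       names(tab)[hit[1, 1]])))
    tab <- tab[, -drop_j, drop = FALSE]
  }
  nzv <- vapply(tab, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    max(table(x)) / length(x)
  }, numeric(1))
  for (nm in names(tab)[nzv > nzv_prop])
    dropped <- rbind(dropped, data.frame(item = nm,
      reason = sprintf("near-zero variance (modal share %.2f)", nzv[nm])))
  tab <- tab[, nzv <= nzv_prop, drop = FALSE]
  if (!ncol(tab)) stopf("all behavioural items dropped by filters")
  attr(tab, "dropped") <- dropped
  tab
}

#' Covariate deconfounding
#'
#' Per-column OLS residualization on intercept + covariates (age, sex, site
#' dummies, mean framewise displacement). Aliased columns of the design are
#' dropped by the pivoted QR with a warning.
#'
#' @param tab data.frame or matrix to residualize.
#' @param covariates data.frame of covariates; factors/characters are
#'   expanded to dummies.
#' @return residualized numeric matrix (same column names).
#' @export
deconfound <- function(tab, covariates) {
  X <- as.matrix(as.data.frame(tab))
  cov_df <- as.data.frame(covariates)
  if (nrow(cov_df) != nrow(X))
    stopf("covariates have %d rows, data has %d", nrow(cov_df), nrow(X))
  mm <- stats::model.matrix(~ ., data = cov_df)
  fit <- lm.fit(mm, X)
  if (fit$rank < ncol(mm))
    warnf("covariate design rank-deficient; %d aliased column(s) dropped",
          ncol(mm) - fit$rank)
  res <- as.matrix(fit$residuals)
  colnames(res) <- colnames(X)
  res
}

#' State-based time-varying and static FNC predictors
#'
#' For every subject: the mean over windows assigned to each state of the
#' mean FNC across the selected top-k pairs (k time-varying predictors),
#' plus the mean of the static FNC over the same pairs (one static
#' predictor). Cells for never-visited states are imputed with the sample
#' mean of that predictor.
#'
#' @param wfnc_list list of `wfnc` objects.
#' @param model a `state_model` fitted on those windows.
#' @param top_pairs integer vector of selected pair indices.
#' @param static_list list of `sfnc` objects (same subject order).
#' @return data.frame: `tv_state1..k`, `static`; attribute `n_imputed`
#'   counts mean-imputed cells.
#' @export
state_predictors <- function(wfnc_list, model, top_pairs, static_list) {
  if (!length(top_pairs)) stopf("top_pairs must be non-empty")
  n <- length(wfnc_list)
  k <- model$k
  tv <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    V <- wfnc_list[[i]]$values[, top_pairs, drop = FALSE]
    a <- model$assignments[[i]]
    prof <- rowMeans(V)
    for (s in seq_len(k)) {
      if (any(a == s)) tv[i, s] <- mean(prof[a == s])
    }
  }
  n_imputed <- 0L
  for (s in seq_len(k)) {
    miss <- is.na(tv[, s])
    if (any(miss)) {
      tv[miss, s] <- mean(tv[!miss, s])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  stat <- vapply(static_list, function(sf) mean(sf$values[top_pairs]),
                 numeric(1))
  out <- as.data.frame(tv)
  names(out) <- paste0("tv_state", seq_len(k))
  out$static <- stat
  attr(out, "n_imputed") <- n_imputed
  out
}

fit_ols <- function(y, X) {
  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df)
  s <- summary(fit)
  n <- length(y)
  p <- fit$rank - 1
  fstat <- s$fstatistic
  list(r2 = s$r.squared, adj_r2 = s$adj.r.squared,
       loglik = as.numeric(logLik(fit)),
       f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       p = if (is.null(fstat)) NA_real_ else
         unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       fitted = fitted(fit))
}

#' Time-varying vs static regression comparison
#'
#' Fits, per behaviour, three OLS models: time-varying (k state predictors),
#' static (1 predictor), and full (k + 1). Model significance is the
#' F-test of the full model against the intercept-only model (one-tailed,
#' uncorrected). For behaviours passing `p_enter`, reports R-squared,
#' adjusted R-squared and log-likelihood per model, whether the
#' time-varying model explains more variance than the static one, and the
#' fitted-vs-observed correlation of the full model.
#'
#' @param predictors data.frame from [state_predictors()].
#' @param behaviours data.frame of (deconfounded) behaviours.
#' @param p_enter model-significance gate (default 0.05).
#' @return data.frame, one row per behaviour, with columns
#'   `r2_tv`, `r2_static`, `r2_full`, `adj_r2_*`, `loglik_*`,
#'   `model_p`, `passes`, `tv_beats_static`, `fit_obs_r`, `fit_obs_ci_*`.
#' @export
compare_regressions <- function(predictors, behaviours, p_enter = 0.05) {
  tv_cols <- grep("^tv_state", names(predictors), value = TRUE)
  if (!length(tv_cols) || !("static" %in% names(predictors)))
    stopf("predictors must contain tv_state* and static columns")
  n <- nrow(predictors)
  if (n <= 10 * (length(tv_cols) + 1))
    warnf("only %d subjects for %d predictors", n, length(tv_cols) + 1)
  behaviours <- as.data.frame(behaviours)
  rows <- lapply(names(behaviours), function(nm) {
    y <- behaviours[[nm]]
    ok <- complete.cases(y, predictors)
    y <- y[ok]
    tv <- fit_ols(y, predictors[ok, tv_cols, drop = FALSE])
    st <- fit_ols(y, predictors[ok, "static", drop = FALSE])
    fu <- fit_ols(y, predictors[ok, c(tv_cols, "static"), drop = FALSE])
    fr <- cor(fu$fitted, y)
    zf <- atanh(pmin(fr, 1 - 1e-12))
    se <- 1 / sqrt(length(y) - 3)
    data.frame(behaviour = nm,
               r2_tv = tv$r2, r2_static = st$r2, r2_full = fu$r2,
               adj_r2_tv = tv$adj_r2, adj_r2_static = st$adj_r2,
               adj_r2_full = fu$adj_r2,
               loglik_tv = tv$loglik, loglik_static = st$loglik,
               loglik_full = fu$loglik,
               model_p = fu$p,
               passes = !is.na(fu$p) && fu$p < p_enter,
               tv_beats_static = tv$r2 > st$r2,
               fit_obs_r = fr,
               fit_obs_ci_lo = tanh(zf - 1.96 * se),
               fit_obs_ci_hi = tanh(zf + 1.96 * se))
  })
  do.call(rbind, rows)
}

nagelkerke_r2 <- function(fit, n) {
  d0 <- fit$null.deviance; d1 <- fit$deviance
  cox <- 1 - exp((d1 - d0) / n)
  cox / (1 - exp(-d0 / n))
}

#' Logistic case-control comparison of time-varying vs static FNC
#'
#' Maximum-likelihood logistic regressions of diagnosis on the k
#' time-varying state predictors and on the single static predictor,
#' reporting Nagelkerke pseudo-R-squared, log-likelihood, per-predictor
#' Wald statistics, and BH-FDR-corrected two-sample group-difference
#' t-tests per predictor. If separation is detected (|coef| > 20) the fit
#' is repeated with a small ridge penalty (1e-4) via penalized IRLS.
#'
#' @param predictors data.frame from [state_predictors()].
#' @param labels 0/1 vector (0 = control, 1 = patient), each class n >= 20.
#' @param q FDR level for the group-difference tests (default 0.05).
#' @return list: `tv` and `static` fits (pseudo_r2, loglik, coef table),
#'   `group_tests` data.frame.
#' @export
logistic_status <- function(predictors, labels, q = 0.05) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 20) stopf("each class needs n >= 20")
  tv_cols <- grep("^tv_state", names(predictors), value = TRUE)
  n <- length(labels)
  fit_one <- function(cols) {
    X <- as.matrix(predictors[, cols, drop = FALSE])
    fit <- suppressWarnings(glm(labels ~ X, family = binomial()))
    if (any(abs(coef(fit)) > 20, na.rm = TRUE)) {
      warnf("separation detected; refitting with ridge 1e-4")
      fit <- ridge_logistic(cbind(1, X), labels, 1e-4)
      co <- data.frame(term = c("(Intercept)", cols), estimate = fit$coef,
                       wald_t = fit$coef / fit$se,
                       p = 2 * pnorm(-abs(fit$coef / fit$se)))
      return(list(pseudo_r2 = fit$pseudo_r2, loglik = fit$loglik, coef = co))
    }
    s <- summary(fit)$coefficients
    list(pseudo_r2 = nagelkerke_r2(fit, n),
         loglik = as.numeric(logLik(fit)),
         coef = data.frame(term = c("(Intercept)", cols),
                           estimate = s[, 1], wald_t = s[, 3], p = s[, 4]))
  }
  tv <- fit_one(tv_cols)
  st <- fit_one("static")
  gt <- do.call(rbind, lapply(c(tv_cols, "static"), function(cc) {
    tt <- t.test(predictors[[cc]][labels == 0], predictors[[cc]][labels == 1])
    data.frame(predictor = cc, t = unname(tt$statistic), p = tt$p.value)
  }))
  gt$q_value <- p.adjust(gt$p, "BH")
  gt$significant <- gt$q_value < q
  list(tv = tv, static = st, group_tests = gt)
}

# penalized IRLS logistic fit (ridge on all coefficients except intercept)
ridge_logistic <- function(X, y, lambda, max_iter = 100) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    H <- crossprod(X, X * wts) + pen
    beta_new <- solve(H, crossprod(X, wts * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta <- as.numeric(beta)
  eta <- as.numeric(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  nn <- length(y)
  cox <- 1 - exp(2 * (ll0 - ll) / nn)
  H <- crossprod(X, X * pmax(mu * (1 - mu), 1e-10)) + pen
  se <- sqrt(diag(solve(H)))
  list(coef = beta, se = se, loglik = ll,
       pseudo_r2 = cox / (1 - exp(2 * ll0 / nn)))
}
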