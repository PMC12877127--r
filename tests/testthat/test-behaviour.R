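test_that("behaviour filters drop collinear and near-constant items", {
  set.seed(1)
  n <- 100
  x <- rnorm(n)
  tab <- data.frame(i1 = x, i2 = x, i3 = rnorm(n))
  out <- filter_behaviours(tab)
  expect_equal(names(out), c("i1", "i3"))
  expect_equal(attr(out, "dropped")$item, "i2")

  tab2 <- data.frame(i1 = rnorm(n), i2 = c(rep(0, 96), rnorm(4)))
  out2 <- filter_behaviours(tab2)
  expect_equal(names(out2), "i1")
  expect_match(attr(out2, "dropped")$reason, "near-zero variance")

  # five items: one |r| = 0.85 pair, one 97 percent constant item
  set.seed(2)
  a <- rnorm(n)
  b <- 0.85 * scale(a)[, 1] + sqrt(1 - 0.85^2) * scale(rnorm(n))[, 1]
  # force the sample correlation very high
  b2 <- a + rnorm(n, sd = 0.3)
  tab3 <- data.frame(a = a, b = b2, c = rnorm(n), d = rnorm(n),
                     e = c(rep(1, 97), 2, 2, 2))
  expect_gt(abs(cor(a, b2)), 0.8)
  out3 <- filter_behaviours(tab3)
  expect_equal(names(out3), c("a", "c", "d"))
  expect_error(filter_behaviours(data.frame(x = rep(1, n), y = rep(2, n))),
               "all behavioural items dropped")
})

test_that("deconfounding removes covariate structure", {
  set.seed(3)
  n <- 200
  cov_df <- data.frame(age = rnorm(n, 19), sex = sample(c("F", "M"), n, TRUE),
                       site = sample(paste0("s", 1:4), n, TRUE),
                       fd = abs(rnorm(n, 0.1, 0.02)))
  # behaviour equal to age: residual vanishes
  res <- deconfound(data.frame(y = cov_df$age), cov_df)
  expect_lt(max(abs(res)), 1e-10)
  # covariate-independent column: residual is just de-meaned
  z <- rnorm(n)
  zo <- lm.fit(stats::model.matrix(~ ., cov_df), z)$residuals
  res2 <- deconfound(data.frame(y = zo + 5), cov_df)
  expect_lt(max(abs(res2[, 1] - zo)), 1e-10)
  # planted site offsets: residual site means vanish
  y <- rnorm(n) + c(s1 = 0, s2 = 2, s3 = -1, s4 = 4)[cov_df$site]
  res3 <- deconfound(data.frame(y = y), cov_df)
  site_means <- tapply(res3[, 1], cov_df$site, mean)
  expect_lt(max(abs(site_means)), 1e-10)
})

test_that("state predictors aggregate the selected pairs as defined", {
  # two subjects, 4 windows, 3 pairs; subject 2 never visits state 2
  V1 <- rbind(c(1, 2, 3), c(2, 3, 4), c(0, 1, 2), c(4, 5, 6))
  V2 <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3), c(4, 4, 4))
  wl <- list(structure(list(values = V1, subject_id = "a"), class = "wfnc"),
             structure(list(values = V2, subject_id = "b"), class = "wfnc"))
  model <- structure(list(k = 2L,
    assignments = list(a = c(1L, 2L, 1L, 2L), b = rep(1L, 4)),
    centroids = matrix(0, 2, 3)), class = "state_model")
  st <- list(structure(list(values = c(10, 20, 30)), class = "sfnc"),
             structure(list(values = c(1, 2, 3)), class = "sfnc"))
  pr <- state_predictors(wl, model, top_pairs = c(1, 3), static_list = st)
  # subject a, state 1: windows 1 and 3, pair means (2, 1) -> mean 1.5
  expect_equal(pr$tv_state1[1], mean(c(mean(c(1, 3)), mean(c(0, 2)))))
  expect_equal(pr$tv_state2[1], mean(c(mean(c(2, 4)), mean(c(4, 6)))))
  # subject b, state 1 = grand mean over windows of selected pairs
  expect_equal(pr$tv_state1[2], mean(rowMeans(V2[, c(1, 3)])))
  # never-visited state imputed with the sample mean (here: subject a's value)
  expect_equal(pr$tv_state2[2], pr$tv_state2[1])
  expect_equal(attr(pr, "n_imputed"), 1L)
  expect_equal(pr$static, c(mean(c(10, 30)), mean(c(1, 3))))
  # single selected pair: predictor is that pair's state-conditional mean
  pr1 <- state_predictors(wl, model, top_pairs = 2, static_list = st)
  expect_equal(pr1$tv_state1[1], mean(c(2, 1)))
})

test_that("regression comparison respects nesting and span invariance", {
  set.seed(5)
  n <- 120
  preds <- data.frame(tv_state1 = rnorm(n), tv_state2 = rnorm(n),
                      tv_state3 = rnorm(n), tv_state4 = rnorm(n),
                      static = rnorm(n))
  y <- 0.5 * preds$tv_state1 - 0.4 * preds$static + rnorm(n)
  comp <- compare_regressions(preds, data.frame(y = y))
  expect_gte(comp$r2_full, comp$r2_tv - 1e-12)
  expect_gte(comp$r2_full, comp$r2_static - 1e-12)
  expect_lte(comp$adj_r2_full, comp$r2_full)
  expect_gte(comp$loglik_full, comp$loglik_tv)

  # duplicating the static predictor as a time-varying one leaves the
  # full-model fit unchanged (span argument)
  preds2 <- preds
  preds2$tv_state4 <- preds$static
  comp2 <- compare_regressions(preds2, data.frame(y = y))
  span_r2 <- summary(lm(y ~ tv_state1 + tv_state2 + tv_state3 + static,
                        data = preds))$r.squared
  expect_equal(comp2$r2_full, span_r2, tolerance = 1e-9)
})

test_that("pure-noise behaviours pass the model gate at the nominal rate", {
  set.seed(6)
  n <- 100
  hits <- vapply(1:60, function(i) {
    preds <- data.frame(tv_state1 = rnorm(n), tv_state2 = rnorm(n),
                        static = rnorm(n))
    comp <- compare_regressions(preds, data.frame(y = rnorm(n)))
    comp$passes
  }, logical(1))
  expect_lt(mean(hits), 0.15)
  expect_gt(mean(hits), 0.005)
})

test_that("deconfounded fits obey the Frisch-Waugh property", {
  set.seed(7)
  n <- 150
  cov_df <- data.frame(age = rnorm(n), fd = rnorm(n))
  x <- rnorm(n) + 0.5 * cov_df$age
  y <- 0.8 * x + 0.3 * cov_df$fd + rnorm(n)
  # residualize both, then fit
  rx <- deconfound(data.frame(x = x), cov_df)[, 1]
  ry <- deconfound(data.frame(y = y), cov_df)[, 1]
  b_fw <- coef(lm(ry ~ rx))[2]
  b_joint <- coef(lm(y ~ x + age + fd, data = cbind(cov_df, x = x, y = y)))["x"]
  expect_equal(unname(b_fw), unname(b_joint), tolerance = 1e-6)
})

test_that("logistic comparison reports pseudo-R2 and group contrasts", {
  set.seed(8)
  n <- 160
  preds <- data.frame(tv_state1 = rnorm(n), tv_state2 = rnorm(n),
                      tv_state3 = rnorm(n), tv_state4 = rnorm(n),
                      static = rnorm(n))
  # labels independent of the predictors: pseudo-R2 near zero
  lab0 <- rbinom(n, 1, 0.5)
  r0 <- logistic_status(preds, lab0)
  expect_lt(r0$tv$pseudo_r2, 0.1)
  # labels generated from the state predictors: tv fits better than static
  eta <- 1.5 * preds$tv_state1 - 1.5 * preds$tv_state2
  lab <- rbinom(n, 1, plogis(eta))
  r1 <- logistic_status(preds, lab)
  expect_gt(r1$tv$pseudo_r2, r1$static$pseudo_r2)
  # determinism
  r2 <- logistic_status(preds, lab)
  expect_identical(r1$tv$coef$estimate, r2$tv$coef$estimate)
  expect_error(logistic_status(preds, rep(0:1, c(150, 10))), "n >= 20")
})
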