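test_that("standardization centers, scales, round-trips and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(0, 10, 20))
  st <- standardize_features(X)
  expect_equal(unname(st$Xs[, "a"]), c(-1, 0, 1))
  expect_identical(st$params$dropped, "b")
  expect_equal(apply_standardization(st$params, X), st$Xs)
  expect_error(standardize_features(cbind(a = c(1, 1, 1))), "constant")
})

test_that("one NIPALS component recovers an exactly one-channel response", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, "b"]
  st <- standardize_features(X)
  ys <- (y - mean(y)) / sd(y)
  # first weight vector is proportional to X'y
  fit <- pls_fit(st$Xs, ys, 1)
  w_ref <- drop(crossprod(st$Xs, ys))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(fit$weights[, 1]), abs(w_ref))
  # y exactly linear in one column: full-rank fit reproduces it
  fit3 <- pls_fit(st$Xs, ys, 3)
  expect_equal(drop(st$Xs %*% fit3$coef), ys, tolerance = 1e-10)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  colnames(X) <- letters[1:5]
  y <- rnorm(20)
  st <- standardize_features(X)
  ys <- (y - mean(y)) / sd(y)
  fit <- pls_fit(st$Xs, ys, 5)
  ols <- lsfit(st$Xs, ys)
  pred_pls <- drop(st$Xs %*% fit$coef)
  pred_ols <- ys - ols$residuals
  expect_equal(pred_pls, unname(pred_ols), tolerance = 1e-8)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  tab <- frozen_calibration_table()
  st <- standardize_features(tab[feature_channels()])
  y <- tab$conc_mg_per_L
  fit <- pls_fit(st$Xs, (y - mean(y)) / sd(y), 4)
  G <- crossprod(fit$scores)
  nrm <- sqrt(diag(G))
  off <- abs(G - diag(diag(G))) / tcrossprod(nrm)
  expect_lt(max(off), 1e-8)
  expect_error(pls_fit(st$Xs, (y - mean(y)) / sd(y), 50), "rank")
})

test_that("predictions honor centering, schema order and negative flagging", {
  tab <- frozen_calibration_table()
  model <- pls_calibration(tab, 4)
  expect_equal(as.numeric(pls_predict(model, tab)), model$fitted)
  # a row at the feature means predicts the mean concentration
  center_row <- as.data.frame(as.list(colMeans(tab[feature_channels()])))
  expect_equal(as.numeric(pls_predict(model, center_row)),
               mean(tab$conc_mg_per_L))
  # permuting feature columns changes nothing (matching by name)
  shuffled <- tab[, c("sample_id", "conc_mg_per_L",
                      rev(feature_channels()))]
  expect_equal(as.numeric(pls_predict(model, shuffled)), model$fitted)
  expect_true(is.logical(attr(pls_predict(model, tab), "negative")))
})

test_that("leave-one-out CV has n folds and vanishing error on linear data", {
  tab <- linear_feature_table()
  cv <- pls_cross_validate(tab, 3)
  expect_length(cv$predictions, nrow(tab))
  expect_lt(cv$rmsecv, 1e-8)
  expect_error(pls_cross_validate(tab[1:4, ], 4), "too few")
})

test_that("cross-validated error exceeds calibration error on noisy data", {
  worse <- vapply(1:5, function(s) {
    tab <- linear_feature_table(16)
    set.seed(s)
    tab$conc_mg_per_L <- tab$conc_mg_per_L + rnorm(16, 0, 0.3)
    model <- pls_calibration(tab, 3)
    cal <- calibration_metrics(tab$conc_mg_per_L, model$fitted)
    cv <- pls_cross_validate(tab, 3)
    cv$rmsecv >= cal$rmse
  }, logical(1))
  expect_gte(sum(worse), 4)
})

test_that("calibration metrics reproduce hand-computed regressions", {
  m <- calibration_metrics(1:5, 1:5)
  expect_equal(m[c("r2", "slope", "intercept", "rmse")],
               list(r2 = 1, slope = 1, intercept = 0, rmse = 0))
  m2 <- calibration_metrics(1:5, 1:5 + 1)
  expect_equal(m2$slope, 1)
  expect_equal(m2$intercept, 1)
  expect_equal(m2$rmse, 1)
  # hand arithmetic: x = 1,2,3; y = 2,2,5 -> slope 1.5, intercept -1
  m3 <- calibration_metrics(c(1, 2, 3), c(2, 2, 5))
  expect_equal(m3$slope, 1.5)
  expect_equal(m3$intercept, 0)
  expect_equal(m3$r2, cor(c(1, 2, 3), c(2, 2, 5))^2)
  expect_error(calibration_metrics(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("working-range scan reports all candidates and picks by the rule", {
  tab <- frozen_calibration_table()
  scan <- select_working_range(tab, 4, c(5, 7, 10, 20))
  expect_equal(scan$metrics$upper, c(5, 7, 10, 20))
  expect_true(all(c("r2", "slope", "rmsecv") %in% names(scan$metrics)))
  i <- which(scan$metrics$upper == scan$chosen_upper)
  expect_equal(i, order(abs(scan$metrics$slope - 1), -scan$metrics$r2,
                        scan$metrics$rmsecv)[1])
  single <- select_working_range(tab, 4, 7)
  expect_equal(single$chosen_upper, 7)
  expect_error(select_working_range(tab, 4, c(0.5, 20)), "retains only")
})

test_that("LOD/LOQ follow the 3.3s/m and 10s/m rules with the LOQ floor", {
  lim <- lod_loq(0.09, slope = 1, lowest_standard = 1)
  expect_equal(lim$lod, 0.297)
  expect_equal(lim$loq_unfloored, 0.9)
  expect_equal(lim$loq, 1)
  expect_true(lim$floored)
  free <- lod_loq(0.5, slope = 1, lowest_standard = 1)
  expect_false(free$floored)
  expect_equal(free$loq / free$lod, 10 / 3.3)
  degen <- lod_loq(0, slope = 2)
  expect_true(degen$degenerate)
  expect_equal(degen$lod, 0)
  expect_error(lod_loq(0.1, slope = 0), "slope")
})

test_that("biplot reproduces standardized X at rank 2 and signs are stable", {
  # rank-2 features: reconstruction from 2 components is exact
  set.seed(5)
  Z <- cbind(seq(0, 10, length.out = 14), rnorm(14))
  feats <- Z %*% matrix(rnorm(20), 2, 10)
  colnames(feats) <- feature_channels()
  tab <- cbind(data.frame(sample_id = 1:14,
                          conc_mg_per_L = seq(0, 10, length.out = 14)),
               as.data.frame(feats))
  bip <- pca_biplot(tab)
  Xs <- standardize_features(tab[feature_channels()])$Xs
  recon <- bip$scores %*% t(bip$loadings)
  expect_equal(recon, Xs, tolerance = 1e-8, ignore_attr = TRUE)
  # duplicating every row leaves loading directions unchanged
  bip2 <- pca_biplot(rbind(tab, tab))
  dirs <- function(L) apply(L, 2, function(v) v / sqrt(sum(v^2)))
  expect_equal(abs(dirs(bip2$loadings)), abs(dirs(bip$loadings)),
               tolerance = 1e-8)
})

test_that("repeatability summary matches closed-form statistics", {
  s <- repeatability_summary(c(4, 5, 6), nominal = 5)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 1)
  expect_equal(s$rsd_percent, 20)
  expect_equal(s$accuracy_percent, 100)
  cst <- repeatability_summary(c(3, 3, 3), nominal = 6)
  expect_equal(cst$sd, 0)
  expect_equal(cst$rsd_percent, 0)
  expect_equal(cst$accuracy_percent, 50)
  expect_error(repeatability_summary(5, nominal = 5), "at least 2")
})

test_that("standard addition inverts a constructed linear response", {
  added <- c(0, 2, 4, 6)
  expect_equal(standard_addition_estimate(added, 0.5 + 0.2 * added),
               0.5 / 0.2)
  # constructed so the x-intercept magnitude is 13.6
  b <- 0.04
  expect_equal(standard_addition_estimate(added, b * 13.6 + b * added), 13.6)
  expect_equal(standard_addition_estimate(added, 2 * (b * 13.6 + b * added)),
               13.6)
  expect_equal(standard_addition_estimate(added, 0.2 * added), 0)
  expect_error(standard_addition_estimate(added, 5 - 0.2 * added),
               "positive")
  expect_error(standard_addition_estimate(c(1, 2, 3), c(1, 2, 3)), "zero")
})
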