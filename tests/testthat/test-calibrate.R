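test_that("PLS handles the degenerate and full-rank limits", {
  set.seed(1)
  X <- matrix(rnorm(250), 50, 5)
  # constant response: zero coefficients, intercept = mean(y)
  f0 <- pls_fit(X, rep(7, 50), n_lv = 3)
  expect_equal(f0$coefficients, rep(0, 5))
  expect_equal(f0$intercept, 7)
  # full-rank tall problem with all components = ordinary least squares
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(50, 0, 0.3)
  f <- pls_fit(X, y, n_lv = 5)
  ols <- lm.fit(cbind(1, X), y)
  pred_ols <- drop(cbind(1, X) %*% ols$coefficients)
  expect_lt(max(abs(f$fitted - pred_ols)), 1e-6)
  # successive scores orthogonal
  expect_lt(max(abs(crossprod(f$scores) - diag(diag(crossprod(f$scores))))),
            1e-8)
  expect_error(pls_fit(X, y, n_lv = 50), "n_lv")
})

test_that("PLS recovers a planted single latent direction", {
  set.seed(2)
  w <- rnorm(40); w <- w / sqrt(sum(w^2))
  scores <- rnorm(500, 0, 3)
  X <- scores %*% t(w) + matrix(rnorm(500 * 40, 0, 0.05), 500, 40)
  y <- scores + rnorm(500, 0, 0.1)
  f <- pls_fit(X, y, n_lv = 1)
  expect_gt(abs(cor(f$weights[, 1], w)), 0.99)
})

test_that("PLS prediction is a pure affine map with exact identities", {
  set.seed(3)
  X <- matrix(rnorm(300), 60, 5)
  y <- rnorm(60)
  f <- pls_fit(X, y, n_lv = 3)
  expect_lt(max(abs(predict(f, X) - f$fitted)), 1e-10)
  # the training mean row predicts the training mean response
  expect_lt(abs(predict(f, matrix(colMeans(X), 1)) - mean(y)), 1e-10)
  # permutation equivariance
  p <- sample(60)
  expect_equal(predict(f, X[p, ]), predict(f, X)[p])
  expect_error(predict(f, X[, 1:3]), "column count")
})

test_that("cross-validation tuning is deterministic and reuses partitions", {
  set.seed(4)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(100)
  fam <- pls_family()
  t1 <- cv_tune(X, y, fam, pls_grid(5), seed = 11)
  t2 <- cv_tune(X, y, fam, pls_grid(5), seed = 11)
  expect_identical(t1$rmse, t2$rmse)
  expect_equal(dim(t1$rmse), c(5, 10))
  expect_equal(t1$se, apply(t1$rmse, 1, sd) / sqrt(10))
  # single-point grid works
  t3 <- cv_tune(X, y, fam, pls_grid(2, 2), seed = 1)
  expect_equal(length(t3$mean), 1)
})

test_that("models without pure-noise predictors usually cross-validate better", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 60
    Xs <- matrix(rnorm(n * 3), n, 3)
    y <- drop(Xs %*% c(2, -1, 1)) + rnorm(n, 0, 0.5)
    Xn <- cbind(Xs, matrix(rnorm(n * 30), n, 30))  # plus pure noise
    fam <- pls_family()
    m_clean <- cv_tune(Xs, y, fam, pls_grid(3, 3), seed = s)$mean
    m_noisy <- cv_tune(Xn, y, fam, pls_grid(3, 3), seed = s)$mean
    if (m_clean <= m_noisy) wins <- wins + 1L
  }
  expect_gte(wins, 90)
})

test_that("one-SE rule picks the least complex adequate model", {
  mk <- function(means, ses, cx) {
    structure(list(grid = lapply(cx, function(k) list(n_lv = k)),
                   mean = means, se = ses, complexity = cx,
                   rmse = matrix(means, length(means), 1)),
              class = "tuning_result")
  }
  # threshold 1.85 + 0.1 = 1.95 -> complexity 2 qualifies
  sel <- one_se_select(mk(c(2.0, 1.9, 1.85), c(0.1, 0.1, 0.1), 1:3))
  expect_equal(sel$params$n_lv, 2)
  expect_equal(sel$threshold, 1.95)
  # zero SEs -> argmin
  expect_equal(one_se_select(mk(c(2, 1.9, 1.85), c(0, 0, 0), 1:3))$params$n_lv,
               3)
  # all means equal -> least complex
  expect_equal(one_se_select(mk(c(1, 1, 1), c(0.1, 0.1, 0.1), 1:3))$params$n_lv,
               1)
  # never selects above the threshold
  s <- one_se_select(mk(c(5, 1, 4.9), c(0.5, 0.5, 0.5), 1:3))
  expect_lte(s$mean, 1.5 + 1e-12)
})

test_that("RFE ranks planted predictors highly and respects its contract", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    X <- matrix(rnorm(80 * 50), 80, 50)
    y <- drop(X[, 1:3] %*% c(3, -3, 2)) + rnorm(80, 0, 0.5)
    f <- pls_fit(X, y, n_lv = 5)
    imp <- abs(f$coefficients) * apply(X, 2, sd)
    if (all(1:3 %in% order(imp, decreasing = TRUE)[1:10])) hits <- hits + 1L
  }
  expect_gte(hits, 90)
  # the family importance equals ordering by |standardized coefficient|
  set.seed(5)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(60)
  fam <- pls_family()
  fit <- fam$fit(X, y, list(n_lv = 4))
  expect_equal(order(fam$importance(fit)),
               order(abs(fit$coefficients) * apply(X, 2, sd)))
  # sizes = {p} returns the full predictor set
  r <- rfe(X, y, fam, sizes = 8, grid = pls_grid(3), seed = 1)
  expect_equal(r$selected, 1:8)
  expect_equal(r$chosen_size, 8)
  # end-to-end: planted predictors survive elimination
  set.seed(6)
  X2 <- matrix(rnorm(80 * 50), 80, 50)
  y2 <- drop(X2[, 1:3] %*% c(3, -3, 2)) + rnorm(80, 0, 0.5)
  r2 <- rfe(X2, y2, fam, sizes = c(50, 25, 10, 3), grid = pls_grid(3),
            seed = 2)
  expect_true(r2$chosen_size %in% c(50, 25, 10, 3))
  expect_equal(length(r2$selected), r2$chosen_size)
  nofam <- fam; nofam$importance <- NULL
  expect_error(rfe(X2, y2, nofam, sizes = 8, grid = pls_grid(2)),
               "importance")
})

test_that("auxiliary fusion scales columns and freezes train-time constants", {
  set.seed(7)
  X <- matrix(rnorm(50 * 20), 50, 20)
  aux <- data.frame(sand = runif(50, 0, 100))
  fz <- fuse_auxiliary(X, aux, "pca_scores_99")
  expect_lt(max(abs(colMeans(fz$train))), 1e-10)
  expect_lt(max(abs(apply(fz$train, 2, sd) - 1)), 1e-10)
  # projecting the training data reproduces the fused matrix
  expect_lt(max(abs(fusion_project(fz, X, aux) - fz$train)), 1e-10)
  # scale_only keeps all predictors
  fz2 <- fuse_auxiliary(X, aux, "scale_only")
  expect_equal(ncol(fz2$train), 21)
  # constant auxiliary column is rejected at scaling
  expect_error(fuse_auxiliary(X, data.frame(sand = rep(50, 50)),
                              "scale_only"), "zero variance")
  # missing texture (organic samples) is rejected
  expect_error(fuse_auxiliary(X, data.frame(sand = c(NA, runif(49))),
                              "pca_scores_99"), "missing")
  # recipe invariant: scale_only iff rfe source
  expect_equal(predictor_recipe("rfe", "sand")$fusion, "scale_only")
  expect_equal(predictor_recipe("spectra", "sand")$fusion, "pca_scores_99")
  expect_equal(predictor_recipe("spectra", "none")$fusion, "none")
})

test_that("end-to-end training produces held-out statistics without leakage", {
  lib <- generate_library(90, "mineral", seed = 31)
  mod <- train_model(lib, "mineral", "SG1", seed = 5, grid = pls_grid(8))
  expect_s3_class(mod$stats, "validation_stats")
  expect_equal(mod$stats$n, length(mod$split$test))
  expect_equal(nrow(mod$test), 30)
  # leakage guard: the model must be identical when test-set SOC changes
  lib2 <- lib
  te_ids <- mod$test$sample_id
  i <- match(te_ids, lib2$properties$sample_id)
  lib2$properties$soc[i] <- sample(lib2$properties$soc[i])
  mod2 <- train_model(lib2, "mineral", "SG1", seed = 5, grid = pls_grid(8))
  expect_identical(mod2$fit$coefficients, mod$fit$coefficients)
  expect_identical(mod2$chosen$params, mod$chosen$params)
  # organic + auxiliary is rejected before any computation
  expect_error(train_model(lib, "organic",
                           predictor = predictor_recipe("spectra", "sand")),
               "organic")
})

test_that("a noise-free linear library is recovered almost exactly", {
  # disable clay masking (the nonlinearity) and the sand confound band
  # (which shares the SOC feature shape and so blocks exact inversion):
  # what remains is a linear, injective property-to-spectrum map
  b_lin <- default_bands()
  b_lin$gain[b_lin$driver == "sand"] <- 0
  cat_lin <- band_catalog(
    bands = b_lin,
    baseline = modifyList(band_catalog()$baseline, list(clay_mask = 0)),
    noise = list(scan_sd = 0, scan_sd_sand = 0, lab_sd = 0))
  lib <- generate_library(90, "mineral", seed = 33, catalog = cat_lin)
  mod <- train_model(lib, "mineral", "SG1", seed = 3, grid = pls_grid(12))
  expect_gt(mod$stats$r2, 0.99)
})

test_that("the latent-variable path shortcut equals per-point refits", {
  set.seed(8)
  X <- matrix(rnorm(70 * 25), 70, 25)
  y <- drop(X %*% rnorm(25)) + rnorm(70)
  Xte <- matrix(rnorm(30 * 25), 30, 25)
  yte <- drop(Xte %*% rnorm(25))
  got <- socspec:::pls_path_rmse(X, y, Xte, yte, ks = 1:8)
  want <- vapply(1:8, function(k) {
    f <- pls_fit(X, y, k)
    sqrt(mean((predict(f, Xte) - yte)^2))
  }, numeric(1))
  expect_lt(max(abs(got - want)), 1e-10)
  # and cv_tune takes the same path: identical results with/without it
  fam <- pls_family()
  fam_slow <- fam; fam_slow$cv_path <- NULL
  t_fast <- cv_tune(X, y, fam, pls_grid(6), seed = 3)
  t_slow <- cv_tune(X, y, fam_slow, pls_grid(6), seed = 3)
  expect_equal(t_fast$rmse, t_slow$rmse, tolerance = 1e-12)
})

test_that("an external learner satisfies the family contract", {
  skip_if_not_installed("ranger")
  set.seed(9)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- drop(X %*% c(3, -2, 1, 0, 0, 0)) + rnorm(60, 0, 0.3)
  fam <- rf_family(num_trees = 100)
  fit <- fam$fit(X, y, list(mtry = 3))
  pred <- fam$predict(fit, X)
  expect_equal(length(pred), 60)
  expect_gt(cor(pred, y), 0.8)
  imp <- fam$importance(fit)
  expect_equal(length(imp), 6)
  # informative predictors outrank the pure-noise ones
  expect_true(all(rank(-imp)[1:3] <= 3))
})
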