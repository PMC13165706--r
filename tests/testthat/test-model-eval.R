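test_that("venetian-blind folds interleave samples deterministically", {
  f <- venetian_blind_folds(10, 5)
  expect_identical(f$fold_of_row, c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L))

  f7 <- venetian_blind_folds(7, 5)
  expect_identical(unname(as.integer(table(f7$fold_of_row))),
                   c(2L, 2L, 1L, 1L, 1L))

  for (n in c(5, 11, 23, 40)) for (k in c(2, 5)) {
    sizes <- table(venetian_blind_folds(n, k)$fold_of_row)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(length(sizes), k)
  }
  expect_error(venetian_blind_folds(4, 5), "at least")
})

test_that("PCA compression is exact at full rank and leak-free", {
  set.seed(1)
  basis <- matrix(rnorm(20), 10, 2)
  X <- matrix(rnorm(16), 8, 2) %*% t(basis)          # rank 2
  pc <- pca_compress(X, n_components = 2)
  recon <- pc$T_cal %*% t(pc$loadings) + matrix(pc$center, 8, 10, byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_lt(abs(cor(pc$T_cal[, 1], pc$T_cal[, 2])), 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))

  Xv <- matrix(rnorm(30), 3, 10)
  pc2 <- pca_compress(X, Xv, 2)
  expect_equal(pc2$T_cal, pc$T_cal)
  # projecting the calibration matrix itself reproduces the training scores
  expect_equal(sweep(X, 2, pc$center) %*% pc$loadings, pc$T_cal)
  expect_error(pca_compress(X, n_components = 9), "n_components")
})

test_that("learners reproduce training data in their trivial regimes", {
  set.seed(2)
  X <- matrix(rnorm(120), 30, 4)
  cl <- ifelse(X[, 1] + X[, 2] > 0, "A", "B")
  knn1 <- model_spec("kNN", "classification", list(k = 1), pca_components = 3)
  expect_identical(fit_predict(knn1, X, cl, X), cl)

  svm_lin <- model_spec("SVM", "classification", list(kernel = "linear", cost = 100),
                        pca_components = 3)
  sep <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  sep_cl <- rep(c("A", "B"), each = 20)
  expect_identical(fit_predict(svm_lin, sep, sep_cl, sep), sep_cl)

  rf <- model_spec("RF", "regression", list(n_trees = 200, max_depth = 10),
                   pca_components = 3)
  y <- X[, 1] + rnorm(30, 0, 0.1)
  expect_identical(fit_predict(rf, X, y, X, seed = 5),
                   fit_predict(rf, X, y, X, seed = 5))
})

test_that("manhattan kNN matches a hand-computed neighbour set", {
  X_cal <- rbind(c(0, 0), c(10, 0), c(0, 10))
  y_cal <- c(1, 2, 30)
  X_val <- matrix(c(1, 2), 1)   # manhattan distances: 3, 11, 9
  knn2 <- model_spec("kNN", "regression", list(k = 2, metric = "manhattan"),
                     pca_components = 2)
  expect_equal(fit_predict(knn2, X_cal, y_cal, X_val), mean(c(1, 30)))
  knn2e <- model_spec("kNN", "regression", list(k = 2, metric = "euclidean"),
                      pca_components = 2)
  # euclidean distances: sqrt(5), sqrt(85), sqrt(65) -> neighbours 1 and 3
  expect_equal(fit_predict(knn2e, X_cal, y_cal, X_val), mean(c(1, 30)))
})

test_that("regression metrics match hand arithmetic", {
  y <- c(0, 1, 2, 3)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m), c(r2 = 1, rmse = 0, mae = 0))

  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$r2, 0)

  m3 <- regression_metrics(y, c(0, 1, 2, 7))
  expect_equal(m3$rmse, 2)
  expect_equal(m3$mae, 1)
  expect_error(regression_metrics(rep(1, 4), y), "zero variance")
})

test_that("classification metrics match the printed definitions", {
  perfect <- matrix(c(5, 0, 0, 0, 7, 0, 0, 0, 4), 3, 3)
  m <- classification_metrics(perfect)
  expect_equal(unlist(m), c(accuracy = 1, ba = 1, f1_macro = 1, mcc = 1))

  anti <- matrix(c(0, 5, 5, 0), 2, 2)
  suppressMessages(m2 <- classification_metrics(anti))
  expect_equal(m2$accuracy, 0)
  expect_equal(m2$mcc, -1)

  cm <- matrix(c(3, 2, 1, 4), 2, 2, byrow = FALSE,
               dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  cm[] <- c(3, 2, 1, 4)  # rows: true A = (3,1), true B = (2,4)
  m3 <- classification_metrics(cm)
  # brute-force per-sample counting over the 10 samples
  y_true <- rep(c("A", "A", "B", "B"), c(3, 1, 2, 4))
  y_pred <- rep(c("A", "B", "A", "B"), c(3, 1, 2, 4))
  orc <- oracle_classification_metrics(y_true, y_pred, c("A", "B"))
  expect_equal(m3, orc, tolerance = 1e-12)
  # binary MCC printed formula
  tp <- 3; tn <- 4; fp <- 2; fn <- 1
  expect_equal(m3$mcc,
               (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
})

test_that("balanced accuracy equals accuracy only under class balance", {
  balanced <- matrix(c(8, 2, 2, 8), 2, 2)
  mb <- classification_metrics(balanced)
  expect_equal(mb$accuracy, mb$ba)

  # majority-vote classifier on imbalanced classes: high accuracy, BA 0.5
  imb <- matrix(c(74, 26, 0, 0), 2, 2)
  suppressMessages(mi <- classification_metrics(imb))
  expect_equal(mi$accuracy, 0.74)
  expect_equal(mi$ba, 0.5)
  expect_gt(mi$accuracy, mi$ba)
})

test_that("bootstrap evaluation is seeded and exact for a perfect classifier", {
  set.seed(3)
  sep <- rbind(matrix(rnorm(60, -4), 30, 2), matrix(rnorm(60, 4), 30, 2))
  cl <- rep(c("A", "B"), each = 30)
  pp <- preprocess_spec("none", FALSE, 1, 2, 0, "mean_center")
  svm_lin <- model_spec("SVM", "classification", list(kernel = "linear", cost = 10),
                        pca_components = 2)
  b1 <- bootstrap_eval(svm_lin, pp, sep, cl, B = 25, seed = 4)
  expect_equal(b1$metrics$ba, 1)
  b2 <- bootstrap_eval(svm_lin, pp, sep, cl, B = 25, seed = 4)
  expect_identical(b1$metrics, b2$metrics)
})

test_that("bootstrap means stabilise as B grows", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(40, 0, 0.5)
  pp <- preprocess_spec("none", FALSE, 1, 2, 0, "mean_center")
  pls3 <- model_spec("PLS", "regression", list(n_lv = 3))
  b100 <- bootstrap_eval(pls3, pp, X, y, B = 100, seed = 6)
  b1000 <- bootstrap_eval(pls3, pp, X, y, B = 1000, seed = 7)
  # Monte-Carlo SE of the difference of the two independent means; 3 SEs so
  # the deterministic suite's false-alarm rate is negligible
  se <- sqrt(b100$metric_sd$rmse^2 / b100$iterations_used +
             b1000$metric_sd$rmse^2 / b1000$iterations_used)
  expect_lt(abs(b100$metrics$rmse - b1000$metrics$rmse), 3 * se)
})

test_that("per-fold refitting differs from a leaky whole-set transform", {
  set.seed(6)
  X <- matrix(rnorm(40 * 8), 40, 8)
  X[1:8, ] <- X[1:8, ] * 30          # gross scale heterogeneity across folds
  y <- as.numeric(X %*% rnorm(8)) + rnorm(40)
  pp <- preprocess_spec("none", FALSE, 1, 2, 0, "autoscale")
  folds <- venetian_blind_folds(40, 5)
  honest <- cross_validate(model_spec("PLS", "regression", list(n_lv = 3)),
                           pp, X, y, folds)
  # leaky variant: transform once on all rows, then cross-validate raw
  X_leak <- preprocess_fit_apply(pp, X)$X_cal
  leaky_res <- numeric(40)
  for (k in 0:4) {
    test <- folds$fold_of_row == k
    m <- fit_pls(X_leak[!test, ], y[!test], 3)
    leaky_res[test] <- predict(m, X_leak[test, , drop = FALSE])
  }
  leaky <- regression_metrics(y, leaky_res)
  expect_false(isTRUE(all.equal(honest$metrics$rmse, leaky$rmse)))
})

test_that("grid search returns the argmin and is monotone in the candidate set", {
  set.seed(7)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.numeric(X %*% c(2, 1, 0, 0, 0, 0)) + rnorm(40, 0, 0.3)
  pp <- preprocess_spec("none", FALSE, 1, 2, 0, "mean_center")
  good <- model_spec("PLS", "regression", list(n_lv = 3))
  single <- grid_search("regression", list(pp), list(good), X, y, "VB5", seed = 1)
  expect_identical(single$best$model_id, model_id(good))

  worse <- model_spec("kNN", "regression", list(k = 39), pca_components = 2)
  both <- grid_search("regression", list(pp), list(good, worse), X, y, "VB5",
                      seed = 1)
  expect_identical(both$best$model_id, single$best$model_id)
  expect_lte(both$best$metrics$rmse, min(both$leaderboard$rmse))
})
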