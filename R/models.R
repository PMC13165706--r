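# Model specification and fitting -------------------------------------------

#' Specify a calibration or classification model
#'
#' @param family `"PLS"`, `"kNN"`, `"RF"` or `"SVM"`.
#' @param task `"regression"` or `"classification"` (PLS is
#'   regression-only).
#' @param hyperparameters named list: PLS `n_lv`; kNN `k` and `metric`
#'   (`"euclidean"` or `"manhattan"`); RF `n_trees` (200-500) and
#'   `max_depth` (10-20); SVM `kernel` (`"linear"`, `"polynomial"`,
#'   `"rbf"`, `"sigmoid"`), `cost`, optional `gamma`/`degree`.
#' @param pca_components number of principal components the predictors are
#'   compressed to before fitting; required for kNN, RF and SVM, must be
#'   `NULL` for PLS (which performs its own projection).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("PLS", "kNN", "RF", "SVM"),
                       task = c("regression", "classification"),
                       hyperparameters = list(), pca_components = NULL) {
  family <- match.arg(family)
  task <- match.arg(task)
  hp <- hyperparameters
  if (family == "PLS") {
    assert_that(task == "regression", "PLS models here are regression-only")
    assert_that(is.null(pca_components), "PLS does not use PCA compression")
    assert_that(!is.null(hp$n_lv) && hp$n_lv >= 1, "PLS needs n_lv >= 1")
  } else {
    assert_that(!is.null(pca_components) && pca_components >= 1,
                "%s requires pca_components", family)
  }
  if (family == "kNN") {
    assert_that(!is.null(hp$k) && hp$k >= 1, "kNN needs k >= 1")
    hp$metric <- if (is.null(hp$metric)) "euclidean" else hp$metric
    assert_that(hp$metric %in% c("euclidean", "manhattan"),
                "kNN metric must be euclidean or manhattan")
  }
  if (family == "RF") {
    hp$n_trees <- if (is.null(hp$n_trees)) 500L else as.integer(hp$n_trees)
    hp$max_depth <- if (is.null(hp$max_depth)) 20L else as.integer(hp$max_depth)
    assert_that(hp$n_trees >= 200 && hp$n_trees <= 500,
                "RF n_trees must lie in 200..500")
    assert_that(hp$max_depth >= 10 && hp$max_depth <= 20,
                "RF max_depth must lie in 10..20")
  }
  if (family == "SVM") {
    hp$kernel <- if (is.null(hp$kernel)) "linear" else hp$kernel
    assert_that(hp$kernel %in% c("linear", "polynomial", "rbf", "sigmoid"),
                "SVM kernel must be linear, polynomial, rbf or sigmoid")
    hp$cost <- if (is.null(hp$cost)) 1 else hp$cost
  }
  structure(list(family = family, task = task, hyperparameters = hp,
                 pca_components = pca_components),
            class = "model_spec")
}

#' Short id of a model specification
#' @param spec a [model_spec()].
#' @return character id.
#' @export
model_id <- function(spec) {
  hp <- spec$hyperparameters
  detail <- switch(spec$family,
    PLS = sprintf("n_lv=%d", hp$n_lv),
    kNN = sprintf("k=%d,%s", hp$k, hp$metric),
    RF  = sprintf("trees=%d,depth=%d", hp$n_trees, hp$max_depth),
    SVM = sprintf("%s,C=%g", hp$kernel, hp$cost))
  pc <- if (is.null(spec$pca_components)) "" else sprintf(",PC=%d", spec$pca_components)
  sprintf("%s(%s%s)", spec$family, detail, pc)
}

#' Venetian-blind fold assignment
#'
#' Row `j` (in stable sample order) goes to fold `(j - 1) mod k` — every
#' k-th sample shares a fold. Deterministic; fold sizes differ by at most
#' one.
#'
#' @param n number of samples (`n >= k`).
#' @param k number of folds.
#' @return object of class `fold_assignment` with 0-based `fold_of_row`.
#' @export
venetian_blind_folds <- function(n, k = 5) {
  assert_that(n >= k, "n (%d) must be at least k (%d)", n, k)
  structure(list(fold_of_row = (seq_len(n) - 1L) %% as.integer(k),
                 k = as.integer(k)),
            class = "fold_assignment")
}

#' PCA compression fitted on calibration rows
#'
#' Centring and loadings are estimated from the calibration rows only;
#' validation rows are projected onto the calibration loadings. No
#' rescaling beyond the pre-processing already applied.
#'
#' @param X_cal calibration matrix.
#' @param X_val optional validation matrix.
#' @param n_components `1 <= n_components <= min(nrow(X_cal) - 1, ncol)`.
#' @return list with `T_cal`, `T_val` (or `NULL`), `loadings`, `center`,
#'   `explained_variance`.
#' @export
pca_compress <- function(X_cal, X_val = NULL, n_components) {
  assert_matrix(X_cal, "X_cal")
  amax <- min(nrow(X_cal) - 1, ncol(X_cal))
  assert_that(n_components >= 1 && n_components <= amax,
              "n_components must lie in 1..%d (got %s)", amax, n_components)
  ctr <- colMeans(X_cal)
  Xc <- sweep(X_cal, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = n_components)
  loadings <- sv$v
  T_cal <- Xc %*% loadings
  T_val <- if (is.null(X_val)) NULL else sweep(X_val, 2, ctr) %*% loadings
  list(T_cal = T_cal, T_val = T_val, loadings = loadings, center = ctr,
       explained_variance = (sv$d[seq_len(n_components)]^2) / (nrow(X_cal) - 1))
}

# kNN with euclidean or manhattan distance; regression = neighbour mean,
# classification = majority vote (ties: smaller summed distance, then
# alphabetical class name).
knn_predict <- function(X_cal, y_cal, X_val, k, metric = "euclidean") {
  k <- min(k, nrow(X_cal))
  D <- if (metric == "euclidean") {
    sq <- outer(rowSums(X_val^2), rowSums(X_cal^2), "+") -
      2 * X_val %*% t(X_cal)
    sqrt(pmax(sq, 0))
  } else {
    t(apply(X_val, 1, function(v) colSums(abs(t(X_cal) - v))))
  }
  D <- matrix(D, nrow = nrow(X_val))
  if (is.numeric(y_cal)) {
    apply(D, 1, function(d) mean(y_cal[order(d)[seq_len(k)]]))
  } else {
    y_cal <- as.character(y_cal)
    apply(D, 1, function(d) {
      nb <- order(d)[seq_len(k)]
      votes <- table(y_cal[nb])
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1) {
        dist_sum <- vapply(top, function(cl) sum(d[nb][y_cal[nb] == cl]), 0)
        top <- top[order(dist_sum, top)]
      }
      top[1]
    })
  }
}

#' Fit a model on calibration data and predict validation rows
#'
#' Dispatches to the configured learner: the in-package NIPALS PLS, the
#' in-package kNN, `ranger` random forests or `e1071` support vector
#' machines. Inputs for kNN/RF/SVM are expected to be the PCA scores
#' produced by [pca_compress()] (the caller handles compression).
#' Deterministic given `seed` (only RF is stochastic).
#'
#' @param spec a [model_spec()].
#' @param X_cal,y_cal calibration data; `y_cal` a factor or character for
#'   classification.
#' @param X_val rows to predict.
#' @param seed integer seed for the RF learner.
#' @return numeric vector (regression) or character vector
#'   (classification).
#' @export
fit_predict <- function(spec, X_cal, y_cal, X_val, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  assert_matrix(X_cal, "X_cal")
  X_val <- as.matrix(X_val)
  classify <- spec$task == "classification"
  if (classify) y_cal <- factor(y_cal)
  hp <- spec$hyperparameters
  out <- switch(spec$family,
    PLS = {
      amax <- min(nrow(X_cal) - 1, ncol(X_cal))
      m <- tryCatch(fit_pls(X_cal, y_cal, min(hp$n_lv, amax)),
                    error = function(e) stop_nir("PLS training failed: %s",
                                                 conditionMessage(e)))
      predict(m, X_val)
    },
    kNN = knn_predict(X_cal, y_cal, X_val, hp$k, hp$metric),
    RF = {
      df <- data.frame(.y = y_cal, X_cal)
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = hp$n_trees,
                            max.depth = hp$max_depth, seed = seed,
                            num.threads = 1)
      as.vector(stats::predict(fit,
                               data = data.frame(matrix(X_val, nrow(X_val),
                                                        dimnames = list(NULL, colnames(df)[-1]))),
                               num.threads = 1)$predictions)
    },
    SVM = {
      kernel <- if (hp$kernel == "rbf") "radial" else hp$kernel
      args <- list(x = X_cal, y = y_cal, kernel = kernel, cost = hp$cost,
                   scale = FALSE)
      if (!is.null(hp$gamma)) args$gamma <- hp$gamma
      if (!is.null(hp$degree)) args$degree <- hp$degree
      fit <- tryCatch(do.call(e1071::svm, args),
                      error = function(e) stop_nir("SVM training failed: %s",
                                                   conditionMessage(e)))
      as.vector(stats::predict(fit, X_val))
    })
  if (classify) as.character(out) else as.numeric(out)
}
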