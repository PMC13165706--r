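# Cross-validation, bootstrap and grid search -------------------------------

#' Cross-validated evaluation of one pre-processing x model combination
#'
#' For each fold, the pre-processing chain and (for kNN/RF/SVM) the PCA
#' compression are refitted on the training rows only, the model is fitted
#' and the held-out rows are scored. Held-out predictions are pooled across
#' folds before the metrics are computed.
#'
#' @param model a [model_spec()].
#' @param preproc a [preprocess_spec()].
#' @param X,y data in stable sample order.
#' @param folds a [venetian_blind_folds()] assignment (or label vector).
#' @param grid_step wavelength step forwarded to derivative scaling.
#' @param seed seed forwarded to stochastic learners.
#' @return object of class `evaluation_result`: model/preproc ids, scheme
#'   `"VB5"`-style pooled metrics, pooled predictions.
#' @export
cross_validate <- function(model, preproc, X, y, folds, grid_step = 1,
                           seed = 1L) {
  fold_vec <- fold_vector(folds, nrow(X))
  classify <- model$task == "classification"
  pred <- if (classify) character(nrow(X)) else numeric(nrow(X))
  for (k in unique(fold_vec)) {
    test <- fold_vec == k
    assert_that(sum(test) >= 1, "empty fold")
    prep <- preprocess_fit_apply(preproc, X[!test, , drop = FALSE],
                                 X[test, , drop = FALSE], grid_step)
    Xc <- prep$X_cal; Xv <- prep$X_val
    if (!is.null(model$pca_components)) {
      nc <- min(model$pca_components, nrow(Xc) - 1, ncol(Xc))
      pc <- pca_compress(Xc, Xv, nc)
      Xc <- pc$T_cal; Xv <- pc$T_val
    }
    pred[test] <- fit_predict(model, Xc, y[!test], Xv, seed = seed)
  }
  metrics <- if (classify) {
    classification_metrics(confusion_matrix(y, pred))
  } else {
    regression_metrics(y, pred)
  }
  structure(list(model = model, model_id = model_id(model),
                 preproc = preproc, preproc_id = preprocess_id(preproc),
                 cv_scheme = sprintf("VB%d", length(unique(fold_vec))),
                 task = model$task, metrics = metrics, predictions = pred,
                 n = nrow(X)),
            class = "evaluation_result")
}

#' Bootstrap evaluation
#'
#' `B` iterations: draw `n` samples with replacement as the calibration
#' set, refit pre-processing (and PCA) inside the iteration, score the
#' out-of-bag rows, and average the per-iteration metrics. Iterations with
#' an empty out-of-bag set, or (for classification) with a class missing
#' from either side, are skipped.
#'
#' @inheritParams cross_validate
#' @param B bootstrap iterations (default 100).
#' @param seed integer seed; identical seeds give identical results.
#' @return an `evaluation_result` with scheme `"B<B>"`; metrics are means
#'   over scored iterations, with SDs in `$metric_sd` and the number of
#'   scored iterations in `$iterations_used`.
#' @export
bootstrap_eval <- function(model, preproc, X, y, B = 100, seed,
                           grid_step = 1) {
  seed <- assert_seed(seed)
  assert_that(B >= 1, "B must be >= 1")
  classify <- model$task == "classification"
  n <- nrow(X)
  withr::with_seed(seed, {
    rows <- list()
    for (b in seq_len(B)) {
      cal <- sample(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), cal)
      if (!length(oob)) next
      if (classify &&
          (length(unique(y[cal])) < length(unique(y)) ||
           length(unique(y[oob])) < length(unique(y)))) next
      if (!classify && stats::sd(y[oob]) == 0) next
      prep <- preprocess_fit_apply(preproc, X[cal, , drop = FALSE],
                                   X[oob, , drop = FALSE], grid_step)
      Xc <- prep$X_cal; Xv <- prep$X_val
      if (!is.null(model$pca_components)) {
        nc <- min(model$pca_components, nrow(Xc) - 1, ncol(Xc))
        pc <- pca_compress(Xc, Xv, nc)
        Xc <- pc$T_cal; Xv <- pc$T_val
      }
      pred <- fit_predict(model, Xc, y[cal], Xv, seed = seed + b)
      m <- if (classify) {
        classification_metrics(confusion_matrix(y[oob], pred,
                                                classes = sort(unique(as.character(y)))))
      } else {
        regression_metrics(y[oob], pred)
      }
      rows[[length(rows) + 1L]] <- unlist(m)
    }
    if (!length(rows)) {
      stop_nir("bootstrap_eval: no iteration could be scored (class missing from all draws?)")
    }
    M <- do.call(rbind, rows)
    structure(list(model = model, model_id = model_id(model),
                   preproc = preproc, preproc_id = preprocess_id(preproc),
                   cv_scheme = sprintf("B%d", B), task = model$task,
                   metrics = as.list(colMeans(M)),
                   metric_sd = as.list(apply(M, 2, stats::sd)),
                   iterations_used = nrow(M), n = n),
              class = "evaluation_result")
  })
}

#' @export
print.evaluation_result <- function(x, ...) {
  met <- paste(sprintf("%s=%.3f", names(x$metrics), unlist(x$metrics)),
               collapse = ", ")
  cat(sprintf("<evaluation_result> %s | %s | %s | %s\n",
              x$model_id, x$preproc_id, x$cv_scheme, met))
  invisible(x)
}

eval_to_row <- function(ev, target = NA_character_, band_selected = FALSE,
                        n_vars = NA_integer_) {
  base <- data.frame(target = target, model = ev$model_id,
                     preprocessing = ev$preproc_id, cv_scheme = ev$cv_scheme,
                     band_selected = band_selected, n_vars = n_vars,
                     stringsAsFactors = FALSE)
  cbind(base, as.data.frame(ev$metrics))
}

model_complexity <- function(spec) {
  if (spec$family == "PLS") spec$hyperparameters$n_lv else spec$pca_components
}

#' Exhaustive grid search over pre-processing chains and models
#'
#' Evaluates every candidate pre-processing x model combination under the
#' requested validation scheme and returns the winner: minimal RMSE for
#' regression, maximal macro-F1 for classification (the tuning criteria),
#' with ties broken by fewer latent variables / principal components, then
#' by lexicographic pre-processing id. The full leaderboard is retained.
#'
#' @param task `"regression"` or `"classification"`.
#' @param preprocs list of [preprocess_spec()] candidates.
#' @param models list of [model_spec()] candidates.
#' @param X,y data.
#' @param cv_scheme `"VB5"` (Venetian-blind 5-fold) or `"B100"` (bootstrap,
#'   100 iterations).
#' @param seed integer seed.
#' @param grid_step wavelength step for derivative scaling.
#' @return list with `best` (an `evaluation_result`), `leaderboard`
#'   (data.frame, one row per combination) and `failures`.
#' @export
grid_search <- function(task, preprocs, models, X, y,
                        cv_scheme = c("VB5", "B100"), seed = 1L,
                        grid_step = 1) {
  cv_scheme <- match.arg(cv_scheme)
  assert_that(length(preprocs) > 0 && length(models) > 0,
              "candidate sets must be non-empty")
  seed <- assert_seed(seed)
  results <- list(); failures <- character()
  lb <- NULL
  for (pp in preprocs) for (md in models) {
    assert_that(md$task == task, "model task does not match grid task")
    ev <- tryCatch({
      if (cv_scheme == "VB5") {
        cross_validate(md, pp, X, y, venetian_blind_folds(nrow(X), 5),
                       grid_step, seed)
      } else {
        bootstrap_eval(md, pp, X, y, B = 100, seed = seed,
                       grid_step = grid_step)
      }
    }, error = function(e) e)
    if (inherits(ev, "error")) {
      failures <- c(failures, sprintf("%s | %s: %s", model_id(md),
                                      preprocess_id(pp), conditionMessage(ev)))
      next
    }
    results[[length(results) + 1L]] <- ev
    lb <- rbind(lb, eval_to_row(ev, n_vars = ncol(X)))
  }
  if (!length(results)) {
    stop_nir("grid_search: all candidates failed:\n%s",
             paste(failures, collapse = "\n"))
  }
  crit <- if (task == "regression") {
    vapply(results, function(r) r$metrics$rmse, 0)
  } else {
    -vapply(results, function(r) r$metrics$f1_macro, 0)
  }
  cplx <- vapply(results, function(r) model_complexity(r$model), 0)
  pid <- vapply(results, function(r) r$preproc_id, "")
  best <- results[[order(crit, cplx, pid)[1]]]
  list(best = best, leaderboard = lb, failures = failures)
}
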