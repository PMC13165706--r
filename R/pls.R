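# NIPALS partial least squares ----------------------------------------------

#' Fit a univariate PLS regression model (NIPALS)
#'
#' Classical NIPALS with deflation of X only; the y-loading of each
#' component is recomputed from the current residual response. With the
#' maximum number of components (`n_lv = min(n - 1, p)`) and a full-rank
#' predictor matrix the model reproduces ordinary least squares.
#'
#' @param X predictor matrix, n x p.
#' @param y numeric response of length n with positive variance.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param tol inner-loop convergence tolerance.
#' @param max_iter maximum inner iterations per component.
#' @return object of class `pls_model` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, regression coefficients `b` (centred
#'   scale), centring vectors, and per-component explained y-variance `ss`.
#' @export
fit_pls <- function(X, y, n_lv, tol = 1e-10, max_iter = 500) {
  assert_matrix(X, "X")
  y <- as.numeric(y)
  assert_that(length(y) == nrow(X), "length(y) must equal nrow(X)")
  assert_that(all(is.finite(y)), "y contains non-finite values")
  n <- nrow(X); p <- ncol(X)
  assert_that(n >= 2, "need at least 2 samples")
  assert_that(stats::sd(y) > 0, "y has zero variance")
  amax <- min(n - 1, p)
  assert_that(n_lv >= 1 && n_lv <= amax,
              "n_lv must lie in 1..min(n-1, p) = 1..%d (got %s)", amax, n_lv)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv); ss <- numeric(n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break                       # response residual exhausted
    w <- w / nw
    # inner NIPALS iteration (converges immediately for univariate y, kept
    # for the general form and the stated tolerance contract)
    for (it in seq_len(max_iter)) {
      tvec <- E %*% w
      w_new <- crossprod(E, f)[, 1]
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    tvec <- as.numeric(E %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-14) break
    pvec <- crossprod(E, tvec)[, 1] / tt
    qa <- sum(f * tvec) / tt
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; q[a] <- qa
    ss[a] <- qa^2 * tt                           # y sum of squares explained
    E <- E - tcrossprod(tvec, pvec)
    f <- f - qa * tvec
    a_used <- a
  }
  assert_that(a_used >= 1, "no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]; ss <- ss[seq_len(a_used)]

  R <- W %*% solve(crossprod(P, W))              # X-space rotation
  coefs <- vapply(seq_len(a_used), function(a) {
    as.numeric(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  }, numeric(p))
  coefs <- matrix(coefs, nrow = p)
  structure(list(n_lv = a_used, W = W, P = P, q = q, scores = Tm,
                 b = coefs[, a_used], b_per_lv = coefs,
                 x_mean = x_mean, y_mean = y_mean, ss = ss),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the training column count.
#' @param n_lv number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == length(object$x_mean),
              "newdata has %d columns, model expects %d",
              ncol(newdata), length(object$x_mean))
  assert_that(n_lv >= 1 && n_lv <= object$n_lv, "n_lv out of fitted range")
  b <- object$b_per_lv[, n_lv]
  as.numeric(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), p = %d\n",
              x$n_lv, length(x$x_mean)))
  invisible(x)
}

#' Variable Importance in Projection
#'
#' Standard VIP: `VIP_j = sqrt(p * sum_a SS_a * (w_ja / ||w_a||)^2 /
#' sum_a SS_a)` where `SS_a` is the y-variance explained by component `a`.
#' Squared VIPs average to exactly 1 over the variables.
#'
#' @param m a fitted `pls_model`.
#' @return non-negative vector of length p.
#' @export
vip <- function(m) {
  stopifnot(inherits(m, "pls_model"))
  assert_that(sum(m$ss) > 0, "model explains no y variance; VIP undefined")
  p <- nrow(m$W)
  Wn <- sweep(m$W, 2, sqrt(colSums(m$W^2)), "/")   # columns already unit norm
  sqrt(p * as.numeric(Wn^2 %*% m$ss) / sum(m$ss))
}

#' Selectivity Ratio
#'
#' Target projection of the predictors onto the normalised regression
#' vector: each variable's explained sum of squares divided by its residual
#' sum of squares. Variables whose residual variance is (numerically) zero
#' are assigned the maximum finite SR observed, with a message.
#'
#' @param m a fitted `pls_model`.
#' @param X the matrix the model was fitted on.
#' @return non-negative vector of length p.
#' @export
selectivity_ratio <- function(m, X) {
  stopifnot(inherits(m, "pls_model"))
  assert_matrix(X, "X")
  Xc <- sweep(X, 2, m$x_mean)
  bn <- m$b / sqrt(sum(m$b^2))
  t_tp <- as.numeric(Xc %*% bn)
  tt <- sum(t_tp^2)
  assert_that(tt > 0, "degenerate target projection (zero score variance)")
  p_tp <- crossprod(Xc, t_tp)[, 1] / tt
  expl <- tt * p_tp^2                       # ||t p_j||^2 per column
  resid <- colSums(Xc^2) - expl
  resid[resid < 0] <- 0
  sr <- rep(NA_real_, length(expl))
  zero <- resid < .Machine$double.eps * 100
  sr[!zero] <- expl[!zero] / resid[!zero]
  if (any(zero)) {
    fill <- if (all(zero)) Inf else max(sr[!zero])
    message(sprintf("selectivity_ratio: %d column(s) with zero residual variance set to max finite SR",
                    sum(zero)))
    sr[zero] <- fill
  }
  sr
}

#' Root mean square error of cross-validation
#'
#' Out-of-fold PLS prediction error: residuals of every held-out sample are
#' pooled before squaring and averaging, so the value is invariant to fold
#' relabelling.
#'
#' @param X,y data.
#' @param n_lv latent variables (capped per fold at `min(n_train - 1, p)`).
#' @param folds fold assignment from [venetian_blind_folds()] or an integer
#'   vector of fold labels of length `nrow(X)`.
#' @return scalar RMSECV.
#' @export
rmsecv <- function(X, y, n_lv, folds) {
  rmsecv_multi(X, y, n_lv, folds)[as.character(n_lv)][[1]]
}

# RMSECV for all component counts 1..max(n_lv) from one fit per fold.
rmsecv_multi <- function(X, y, n_lv, folds) {
  fold_vec <- fold_vector(folds, nrow(X))
  amax_req <- max(n_lv)
  resid <- matrix(NA_real_, nrow(X), amax_req)
  for (k in unique(fold_vec)) {
    test <- fold_vec == k
    assert_that(sum(!test) >= 2, "a training fold has fewer than 2 samples")
    a_cap <- min(amax_req, sum(!test) - 1, ncol(X))
    m <- fit_pls(X[!test, , drop = FALSE], y[!test], a_cap)
    for (a in seq_len(amax_req)) {
      pred <- predict(m, X[test, , drop = FALSE], n_lv = min(a, m$n_lv))
      resid[test, a] <- y[test] - pred
    }
  }
  out <- sqrt(colMeans(resid^2))
  stats::setNames(out, seq_len(amax_req))[as.character(n_lv)]
}

# Accept either a fold_assignment object or a plain label vector.
fold_vector <- function(folds, n) {
  v <- if (inherits(folds, "fold_assignment")) folds$fold_of_row else folds
  assert_that(length(v) == n, "fold assignment length (%d) must be %d",
              length(v), n)
  v
}
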