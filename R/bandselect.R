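# Wavelength selection: VIP/SR intervals -> siPLS -> CARS-PLS ---------------

#' Candidate spectral intervals from VIP and SR profiles
#'
#' Builds the boolean candidacy mask `VIP >= vip_threshold AND SR above its
#' 0.75 quantile`, merges runs of candidates separated by at most `max_gap`
#' non-candidate points, and discards runs shorter than `min_len`. If the
#' combined mask is empty the rule falls back to the VIP criterion alone
#' (reported via a message); if that is also empty an error instructs
#' full-spectrum use.
#'
#' @param diag list with `vip` and `sr` vectors (as returned by [vip()] and
#'   [selectivity_ratio()]).
#' @param min_len minimum interval length in grid points.
#' @param max_gap maximum gap bridged when merging runs.
#' @param vip_threshold VIP cut-off.
#' @param sr_quantile SR quantile cut-off.
#' @return object of class `interval_set`: list of `intervals` (2-column
#'   matrix, half-open `[start, end)` 1-based grid indices) plus the mask.
#' @export
candidate_intervals <- function(diag, min_len = 5, max_gap = 2,
                                vip_threshold = 1.0, sr_quantile = 0.75) {
  assert_that(length(diag$vip) == length(diag$sr),
              "vip and sr must have equal length")
  mask <- diag$vip >= vip_threshold &
          diag$sr > stats::quantile(diag$sr, sr_quantile, names = FALSE)
  if (!any(mask)) {
    message("candidate_intervals: combined VIP/SR mask empty; falling back to VIP criterion alone")
    mask <- diag$vip >= vip_threshold
  }
  if (!any(mask)) {
    stop_nir("no candidate wavelengths at VIP >= %g even after fallback; use the full spectrum",
             vip_threshold)
  }
  iv <- mask_to_intervals(mask, min_len = min_len, max_gap = max_gap)
  if (!nrow(iv)) {
    stop_nir("all candidate runs shorter than min_len = %d; use the full spectrum", min_len)
  }
  structure(list(intervals = iv, mask = mask, p = length(mask)),
            class = "interval_set")
}

# runs of TRUE -> half-open [start, end) intervals with gap merging
mask_to_intervals <- function(mask, min_len = 1, max_gap = 0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(start = starts[r$values], end = ends[r$values] + 1L)
  if (max_gap > 0 && nrow(iv) > 1) {
    merged <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, "start"] - merged[nrow(merged), "end"] <= max_gap) {
        merged[nrow(merged), "end"] <- iv[i, "end"]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
    iv <- merged
  }
  iv[iv[, "end"] - iv[, "start"] >= min_len, , drop = FALSE]
}

interval_indices <- function(iv_row) seq(iv_row[1], iv_row[2] - 1L)

#' Stepwise interval PLS (siPLS) search
#'
#' Forward greedy combination of candidate intervals minimising RMSECV: each
#' interval is first scored alone (inner minimum over 1..`max_n_lv` latent
#' variables); the best is accepted, then the interval whose addition gives
#' the largest RMSECV decrease is appended while the relative improvement is
#' at least `min_improvement`. Ties are broken towards the lower start
#' index, so the search is fully deterministic.
#'
#' @param intervals an [candidate_intervals()] result.
#' @param X,y data on the full grid.
#' @param folds cross-validation folds.
#' @param max_n_lv largest latent-variable count tried.
#' @param min_improvement relative RMSECV gain required to accept a further
#'   interval (default 0.5\%).
#' @return object of class `band_selection_result` with `method = "siPLS"`,
#'   sorted `selected_indices`, the `rmsecv_trajectory` and `chosen_n_lv`.
#' @export
sipls_search <- function(intervals, X, y, folds, max_n_lv = 10,
                         min_improvement = 0.005) {
  stopifnot(inherits(intervals, "interval_set"))
  iv <- intervals$intervals
  assert_that(nrow(iv) >= 1, "need at least one candidate interval")
  assert_matrix(X, "X")

  score <- function(idx) {
    amax <- min(max_n_lv, length(idx))
    rc <- rmsecv_multi(X[, idx, drop = FALSE], y, seq_len(amax), folds)
    list(rmsecv = min(rc), n_lv = which.min(rc))
  }

  remaining <- seq_len(nrow(iv))
  selected <- integer(0)
  idx_sel <- integer(0)
  best <- Inf; best_lv <- 1L
  trajectory <- data.frame(step = integer(), interval = integer(),
                           rmsecv = numeric())
  step <- 0L
  repeat {
    cand_scores <- vapply(remaining, function(j) {
      score(sort(c(idx_sel, interval_indices(iv[j, ]))))$rmsecv
    }, 0)
    ord <- order(cand_scores, iv[remaining, 1])
    j_best <- remaining[ord[1]]
    new_rmse <- cand_scores[ord[1]]
    improved <- !is.finite(best) ||
      (best - new_rmse) / best >= min_improvement
    if (!improved) break
    selected <- c(selected, j_best)
    idx_sel <- sort(c(idx_sel, interval_indices(iv[j_best, ])))
    sc <- score(idx_sel)
    best <- sc$rmsecv; best_lv <- sc$n_lv
    step <- step + 1L
    trajectory <- rbind(trajectory,
                        data.frame(step = step, interval = j_best, rmsecv = best))
    remaining <- setdiff(remaining, j_best)
    if (!length(remaining)) break
  }
  structure(list(method = "siPLS", selected_indices = idx_sel,
                 selected_intervals = iv[selected, , drop = FALSE],
                 rmsecv_trajectory = trajectory,
                 chosen_n_lv = best_lv, rmsecv = best, seed = NA_integer_),
            class = "band_selection_result")
}

#' CARS retention schedule
#'
#' Number of variables retained at iteration `i` of `n_iterations`:
#' `max(round(p * decay^i), min_vars)` — a single-rate exponential decay
#' clipped below at the minimum retention threshold.
#'
#' @param p number of variables.
#' @param n_iterations sampling iterations.
#' @param decay per-iteration retention ratio.
#' @param min_vars minimum retained variable count.
#' @return integer vector of length `n_iterations`.
#' @export
cars_schedule <- function(p, n_iterations = 30, decay = 0.9, min_vars = 30) {
  pmax(round(p * decay^seq_len(n_iterations)), min_vars)
}

#' Competitive Adaptive Reweighted Sampling (CARS-PLS)
#'
#' At iteration `i`, a PLS model is fitted on a Monte-Carlo subset of
#' `mc_fraction` of the samples restricted to the surviving variables;
#' variables are ranked by absolute regression coefficient, the top
#' `r_i = max(round(p * decay^i), min_vars)` are retained by enforced
#' selection, and adaptive reweighted sampling (draws with replacement,
#' probability proportional to `|b|`) thins the survivors further, never
#' below `min_vars`. RMSECV on the surviving set is recorded per iteration
#' and the iteration with minimal RMSECV defines the selection. Fully
#' reproducible from `seed`.
#'
#' @param X,y data.
#' @param folds cross-validation folds for the per-iteration RMSECV.
#' @param n_iterations,decay,min_vars schedule parameters.
#' @param mc_fraction Monte-Carlo calibration fraction per iteration.
#' @param max_n_lv latent-variable cap for the fits.
#' @param seed integer seed.
#' @return object of class `band_selection_result` with `method = "CARS"`.
#' @export
cars_pls <- function(X, y, folds, n_iterations = 30, decay = 0.9,
                     min_vars = 30, mc_fraction = 0.8, max_n_lv = 10, seed) {
  seed <- assert_seed(seed)
  assert_matrix(X, "X", min_cols = 2L)
  p <- ncol(X); n <- nrow(X)
  if (p < min_vars) {
    warning(sprintf("cars_pls: p = %d < min_vars = %d; selection degenerates to the full spectrum",
                    p, min_vars))
    return(structure(list(method = "CARS", selected_indices = seq_len(p),
                          rmsecv_trajectory = data.frame(step = 0L,
                                                         rmsecv = rmsecv_best(X, y, folds, max_n_lv)$rmsecv),
                          chosen_n_lv = rmsecv_best(X, y, folds, max_n_lv)$n_lv,
                          seed = seed),
                     class = "band_selection_result"))
  }
  sched <- cars_schedule(p, n_iterations, decay, min_vars)
  fold_vec <- fold_vector(folds, n)

  withr::with_seed(seed, {
    surv <- seq_len(p)
    history <- vector("list", n_iterations)
    traj <- data.frame(step = seq_len(n_iterations), rmsecv = NA_real_,
                       n_vars = NA_integer_)
    for (i in seq_len(n_iterations)) {
      cal <- sample(n, max(2, round(mc_fraction * n)))
      amax <- min(max_n_lv, length(cal) - 1, length(surv))
      m <- fit_pls(X[cal, surv, drop = FALSE], y[cal], amax)
      wt <- abs(m$b)
      r_i <- min(sched[i], length(surv))
      top <- surv[order(wt, decreasing = TRUE)[seq_len(r_i)]]
      wt_top <- wt[match(top, surv)]
      if (all(wt_top == 0)) wt_top <- rep(1, length(top))
      drawn <- unique(sample(top, r_i, replace = TRUE, prob = wt_top))
      if (length(drawn) < min_vars) {
        extra <- setdiff(top, drawn)
        drawn <- c(drawn, extra[seq_len(min_vars - length(drawn))])
      }
      surv <- sort(drawn)
      sc <- rmsecv_best(X[, surv, drop = FALSE], y, fold_vec, max_n_lv)
      traj$rmsecv[i] <- sc$rmsecv
      traj$n_vars[i] <- length(surv)
      history[[i]] <- surv
    }
    best_i <- which.min(traj$rmsecv)
    best_surv <- history[[best_i]]
    structure(list(method = "CARS", selected_indices = best_surv,
                   rmsecv_trajectory = traj, survivors = history,
                   chosen_n_lv = rmsecv_best(X[, best_surv, drop = FALSE], y,
                                             fold_vec, max_n_lv)$n_lv,
                   seed = seed),
              class = "band_selection_result")
  })
}

# minimum RMSECV over 1..max_n_lv components
rmsecv_best <- function(X, y, folds, max_n_lv) {
  amax <- min(max_n_lv, ncol(X))
  rc <- rmsecv_multi(X, y, seq_len(amax), folds)
  list(rmsecv = min(rc), n_lv = which.min(rc))
}

#' Restrict a matrix to selected wavelengths
#'
#' @param X matrix on the full grid.
#' @param result a `band_selection_result` (or integer index vector).
#' @return column subset of `X` in ascending wavelength order.
#' @export
apply_band_mask <- function(X, result) {
  idx <- if (inherits(result, "band_selection_result")) result$selected_indices
         else as.integer(result)
  assert_that(length(idx) > 0, "empty wavelength selection")
  assert_that(all(idx >= 1 & idx <= ncol(X)),
              "selected index out of range 1..%d", ncol(X))
  X[, sort(unique(idx)), drop = FALSE]
}

#' @export
print.band_selection_result <- function(x, ...) {
  cat(sprintf("<band_selection_result> %s: %d wavelengths, %d LV, RMSECV trajectory %d step(s)\n",
              x$method, length(x$selected_indices), x$chosen_n_lv,
              nrow(x$rmsecv_trajectory)))
  invisible(x)
}
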