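# Spectral pre-processing ---------------------------------------------------

#' Standard Normal Variate transform
#'
#' Standardises every spectrum (row) to mean 0 and sample standard deviation
#' 1 (denominator n-1), correcting multiplicative scatter. Idempotent.
#'
#' @param X absorbance matrix (rows = spectra), >= 2 columns.
#' @return transformed matrix.
#' @export
snv <- function(X) {
  assert_matrix(X, "X", min_cols = 2L)
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  zero <- which(s < .Machine$double.eps * 100)
  if (length(zero)) {
    stop_nir("SNV undefined for zero-variance row(s): %s",
             paste(utils::head(zero, 5), collapse = ", "))
  }
  (X - m) / s
}

#' Multiplicative Scatter Correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, and
#' returns `(x - a) / b`. With no reference given, the column-wise mean of
#' `X` is used (the calibration-mean convention).
#'
#' @param X absorbance matrix.
#' @param reference reference spectrum of length `ncol(X)`, or `NULL`.
#' @return list with `X` (corrected matrix) and `reference` (the spectrum
#'   actually used).
#' @export
msc <- function(X, reference = NULL) {
  assert_matrix(X, "X", min_cols = 2L)
  if (is.null(reference)) reference <- colMeans(X)
  assert_that(length(reference) == ncol(X),
              "reference length (%d) must equal column count (%d)",
              length(reference), ncol(X))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  assert_that(denom > 0, "MSC reference has zero variance")
  b <- as.numeric(X %*% rc) / denom
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    stop_nir("degenerate MSC fit (|slope| < 1e-12) in row(s): %s",
             paste(utils::head(which(abs(b) < 1e-12), 5), collapse = ", "))
  }
  list(X = (X - a) / b, reference = as.numeric(reference))
}

#' Linear detrending
#'
#' Removes from every spectrum the least-squares straight line over the
#' wavelength index, leaving rows orthogonal to constant and linear trends.
#' Idempotent.
#'
#' @param X absorbance matrix, >= 3 columns.
#' @return detrended matrix.
#' @export
detrend_linear <- function(X) {
  assert_matrix(X, "X", min_cols = 3L)
  p <- ncol(X)
  idx <- seq_len(p) - (p + 1) / 2            # centred index
  denom <- sum(idx^2)
  slope <- as.numeric(X %*% idx) / denom
  X - rowMeans(X) - outer(slope, idx)
}

#' Savitzky-Golay filtering
#'
#' Local-polynomial smoothing or derivative computation applied per row,
#' with same-length output: interior points use the central convolution
#' kernel and the ends are handled by fitting the local polynomial at the
#' edges, so polynomials of degree <= `polyorder` are reproduced (or
#' differentiated) exactly everywhere. Derivatives are scaled by
#' `1 / grid_step^deriv`, i.e. expressed per nm, so they are comparable
#' across instrument grids. `window = 1` is the identity (no filtering).
#'
#' @param X absorbance matrix.
#' @param window odd window length (1 = no filtering).
#' @param polyorder polynomial order, 2 or 3 in the standard grid.
#' @param deriv derivative order, 0 (smoothing), 1 or 2; requires
#'   `deriv <= polyorder`.
#' @param grid_step wavelength step in nm used to scale derivatives.
#' @return filtered matrix.
#' @export
savitzky_golay <- function(X, window, polyorder = 2, deriv = 0, grid_step = 1) {
  assert_matrix(X, "X")
  assert_that(window %% 2 == 1, "window must be odd (got %d)", window)
  assert_that(deriv <= polyorder,
              "deriv (%d) must not exceed polyorder (%d)", deriv, polyorder)
  if (window == 1) {
    assert_that(deriv == 0, "window = 1 (no filtering) requires deriv = 0")
    return(X)
  }
  assert_that(window > polyorder,
              "window (%d) must exceed polyorder (%d)", window, polyorder)
  assert_that(ncol(X) >= window,
              "spectrum length (%d) shorter than window (%d)", ncol(X), window)
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = deriv,
          ts = grid_step))
}

#' Define a pre-processing chain
#'
#' An ordered operator chain in the fixed order scatter correction ->
#' detrending -> Savitzky-Golay -> scaling, the order in which combined
#' treatments are conventionally reported.
#'
#' @param scatter `"none"`, `"SNV"` or `"MSC"`.
#' @param detrend logical, apply linear detrending.
#' @param sg_window odd integer in 1, 3, ..., 21 (1 = no filtering).
#' @param sg_polyorder 2 or 3.
#' @param sg_deriv 0, 1 or 2.
#' @param scaling `"none"`, `"mean_center"` or `"autoscale"`.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(scatter = c("none", "SNV", "MSC"), detrend = FALSE,
                            sg_window = 1, sg_polyorder = 2, sg_deriv = 0,
                            scaling = c("none", "mean_center", "autoscale")) {
  scatter <- match.arg(scatter)
  scaling <- match.arg(scaling)
  assert_that(sg_window %in% seq(1, 21, by = 2),
              "sg_window must be odd and within 1..21")
  assert_that(sg_polyorder %in% c(2, 3), "sg_polyorder must be 2 or 3")
  assert_that(sg_deriv %in% 0:2, "sg_deriv must be 0, 1 or 2")
  if (sg_window == 1) {
    assert_that(sg_deriv == 0, "sg_window = 1 implies sg_deriv = 0")
  } else {
    assert_that(sg_window > sg_polyorder, "sg_window must exceed sg_polyorder")
  }
  structure(list(scatter = scatter, detrend = isTRUE(detrend),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv), scaling = scaling),
            class = "preprocess_spec")
}

#' Human-readable id of a pre-processing chain
#'
#' Stable string in the conventional reporting notation, e.g.
#' `"SNV + linear detrending + SG (9) smoothing + mean centring + scaling"`.
#'
#' @param spec a [preprocess_spec()].
#' @return character id.
#' @export
preprocess_id <- function(spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  parts <- character()
  if (spec$scatter != "none") parts <- c(parts, spec$scatter)
  if (spec$detrend) parts <- c(parts, "linear detrending")
  parts <- c(parts,
    if (spec$sg_window == 1) "no Savitzky-Golay filtering"
    else sprintf("SG (%d,%d) %s", spec$sg_window, spec$sg_polyorder,
                 c("smoothing", "1st derivative", "2nd derivative")[spec$sg_deriv + 1]))
  if (spec$scaling == "mean_center") parts <- c(parts, "mean centring")
  if (spec$scaling == "autoscale") parts <- c(parts, "mean centring + scaling")
  paste(parts, collapse = " + ")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", preprocess_id(x), "\n")
  invisible(x)
}

#' Fit a pre-processing chain on calibration spectra and apply it
#'
#' Applies the chain scatter -> detrend -> Savitzky-Golay -> scaling to both
#' matrices. All fitted statistics (the MSC reference spectrum, column means
#' and SDs for centring/autoscaling) are estimated on the calibration rows
#' only and reused unchanged on the validation rows, so no validation
#' information leaks into the transform.
#'
#' @param spec a [preprocess_spec()].
#' @param X_cal calibration matrix.
#' @param X_val optional validation matrix with the same columns.
#' @param grid_step wavelength step (nm) forwarded to the derivative scaling.
#' @return list with `X_cal`, `X_val` (or `NULL`) and `fitted` (a
#'   `fitted_preprocessor` holding the calibration statistics).
#' @export
preprocess_fit_apply <- function(spec, X_cal, X_val = NULL, grid_step = 1) {
  stopifnot(inherits(spec, "preprocess_spec"))
  assert_matrix(X_cal, "X_cal")
  if (!is.null(X_val)) {
    assert_matrix(X_val, "X_val")
    assert_that(ncol(X_val) == ncol(X_cal),
                "X_cal and X_val must have the same column count")
  }
  fitted <- list(spec = spec, msc_reference = NULL,
                 column_means = NULL, column_sds = NULL)

  if (spec$scatter == "SNV") {
    X_cal <- snv(X_cal)
    if (!is.null(X_val)) X_val <- snv(X_val)
  } else if (spec$scatter == "MSC") {
    fit <- msc(X_cal)
    X_cal <- fit$X
    fitted$msc_reference <- fit$reference
    if (!is.null(X_val)) X_val <- msc(X_val, reference = fit$reference)$X
  }
  if (spec$detrend) {
    X_cal <- detrend_linear(X_cal)
    if (!is.null(X_val)) X_val <- detrend_linear(X_val)
  }
  if (spec$sg_window > 1) {
    X_cal <- savitzky_golay(X_cal, spec$sg_window, spec$sg_polyorder,
                            spec$sg_deriv, grid_step)
    if (!is.null(X_val)) {
      X_val <- savitzky_golay(X_val, spec$sg_window, spec$sg_polyorder,
                              spec$sg_deriv, grid_step)
    }
  }
  if (spec$scaling != "none") {
    mu <- colMeans(X_cal)
    fitted$column_means <- mu
    X_cal <- sweep(X_cal, 2, mu)
    if (!is.null(X_val)) X_val <- sweep(X_val, 2, mu)
    if (spec$scaling == "autoscale") {
      sds <- apply(X_cal, 2, stats::sd)
      sds[sds < .Machine$double.eps * 100] <- 1   # flat columns left centred
      fitted$column_sds <- sds
      X_cal <- sweep(X_cal, 2, sds, "/")
      if (!is.null(X_val)) X_val <- sweep(X_val, 2, sds, "/")
    }
  }
  list(X_cal = X_cal, X_val = X_val,
       fitted = structure(fitted, class = "fitted_preprocessor"))
}

#' Enumerate the pre-processing grid
#'
#' Deterministic, duplicate-free enumeration of the chain space: 3 scatter
#' options x 2 detrend x (no filtering + windows 3..21 x polynomial order
#' 2/3 x derivative 0-2, minus combinations with window <= polyorder) x 3
#' scalings — 1044 chains in full.
#'
#' @param scatter,detrend,windows,polyorders,derivs,scalings constraint
#'   vectors; defaults span the full grid.
#' @return list of [preprocess_spec()] objects with unique ids.
#' @export
enumerate_preprocess_grid <- function(scatter = c("none", "SNV", "MSC"),
                                      detrend = c(FALSE, TRUE),
                                      windows = seq(3, 21, by = 2),
                                      polyorders = c(2, 3),
                                      derivs = 0:2,
                                      scalings = c("none", "mean_center", "autoscale")) {
  sg <- list(list(w = 1L, p = 2L, d = 0L))
  for (w in windows) for (po in polyorders) for (d in derivs) {
    if (w > po && d <= po) sg <- c(sg, list(list(w = w, p = po, d = d)))
  }
  out <- list()
  for (sc in scatter) for (dt in detrend) for (g in sg) for (sl in scalings) {
    out[[length(out) + 1L]] <- preprocess_spec(sc, dt, g$w, g$p, g$d, sl)
  }
  ids <- vapply(out, function(s) paste(s$scatter, s$detrend, s$sg_window,
                                       s$sg_polyorder, s$sg_deriv, s$scaling),
                "")
  out[!duplicated(ids)]
}
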