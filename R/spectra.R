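# SpectrumSet container and spectral I/O ------------------------------------

#' Construct a spectrum set
#'
#' The central spectral container: an absorbance matrix (rows = scans,
#' columns = wavelengths, log(1/R) or log(1/T) units) with per-row sample
#' and replicate annotations, optional class labels, and the instrument
#' profile the spectra were recorded on.
#'
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param absorbance numeric matrix, `length(sample_ids)` x
#'   `length(wavelengths)`, no missing values.
#' @param sample_ids,replicate_ids per-row annotations.
#' @param class_labels optional per-row botanical class.
#' @param instrument optional [instrument_profile()].
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, absorbance, sample_ids, replicate_ids,
                         class_labels = NULL, instrument = NULL) {
  absorbance <- as.matrix(absorbance)
  assert_that(is.numeric(wavelengths) && length(wavelengths) >= 1,
              "wavelengths must be numeric")
  assert_that(all(diff(wavelengths) > 0),
              "wavelengths must be strictly increasing")
  assert_that(ncol(absorbance) == length(wavelengths),
              "column count (%d) must equal number of wavelengths (%d)",
              ncol(absorbance), length(wavelengths))
  assert_that(nrow(absorbance) == length(sample_ids) &&
              nrow(absorbance) == length(replicate_ids),
              "sample_ids and replicate_ids must match the row count")
  assert_that(!anyNA(absorbance) && all(is.finite(absorbance)),
              "absorbance must be finite with no missing values")
  if (!is.null(class_labels)) {
    assert_that(length(class_labels) == nrow(absorbance),
                "class_labels must match the row count")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = unname(absorbance),
                 sample_ids = as.character(sample_ids),
                 replicate_ids = as.character(replicate_ids),
                 class_labels = if (is.null(class_labels)) NULL
                                else as.character(class_labels),
                 instrument = instrument),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d scans x %d wavelengths (%g-%g nm)%s\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$instrument)) "" else paste0(", ", x$instrument$name)))
  invisible(x)
}

#' Write a spectrum set to wide CSV
#'
#' Columns: `sample_id`, `replicate_id`, optional `class`, then one column
#' per wavelength with the wavelength (nm, up to 2 decimals) as header.
#'
#' @param s a [spectrum_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  df <- data.frame(sample_id = s$sample_ids, replicate_id = s$replicate_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(s$class_labels)) df$class <- s$class_labels
  mat <- as.data.frame(s$absorbance)
  names(mat) <- formatC(s$wavelengths, format = "f",
                        digits = if (all(s$wavelengths == round(s$wavelengths))) 0 else 2)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from wide CSV
#'
#' Expects the dialect written by [write_spectra_csv()]: leading
#' `sample_id`, `replicate_id` (and optional `class`) columns followed by
#' wavelength columns with decimal-nm headers, strictly increasing.
#'
#' @param path input file.
#' @param instrument optional [instrument_profile()] to attach.
#' @return a [spectrum_set()].
#' @export
read_spectra_csv <- function(path, instrument = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3, "spectra file must have id columns plus wavelengths")
  assert_that(identical(names(df)[1:2], c("sample_id", "replicate_id")),
              "first two columns must be sample_id, replicate_id")
  has_class <- identical(names(df)[3], "class")
  first_wl <- if (has_class) 4L else 3L
  wl_names <- names(df)[first_wl:ncol(df)]
  wl <- suppressWarnings(as.numeric(wl_names))
  assert_that(!anyNA(wl), "non-numeric wavelength header: %s",
              paste(utils::head(wl_names[is.na(wl)], 3), collapse = ", "))
  assert_that(all(diff(wl) > 0),
              "wavelength header is not strictly increasing (duplicate or reordered columns)")
  mat <- as.matrix(df[, first_wl:ncol(df), drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(df[, first_wl:ncol(df), drop = FALSE], 1,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop_nir("non-numeric absorbance values in row %s",
             paste(utils::head(bad, 3), collapse = ", "))
  }
  if (anyNA(mat)) {
    stop_nir("missing absorbance values in row %s",
             paste(utils::head(which(rowSums(is.na(mat)) > 0), 3), collapse = ", "))
  }
  spectrum_set(wl, mat, df$sample_id, df$replicate_id,
               class_labels = if (has_class) df$class else NULL,
               instrument = instrument)
}

#' Average replicate scans
#'
#' Collapses a spectrum set to one row per sample id by arithmetic mean over
#' that sample's replicate rows, mirroring duplicate-aliquot acquisition
#' followed by spectral averaging. Idempotent. Class labels must agree
#' within a sample.
#'
#' @param s a [spectrum_set()].
#' @return a [spectrum_set()] with one row per sample and replicate id
#'   `"mean"`.
#' @export
average_replicates <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  ids <- unique(s$sample_ids)
  out <- matrix(NA_real_, length(ids), length(s$wavelengths))
  classes <- if (is.null(s$class_labels)) NULL else character(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(s$sample_ids == ids[i])
    out[i, ] <- colMeans(s$absorbance[rows, , drop = FALSE])
    if (!is.null(classes)) {
      cl <- unique(s$class_labels[rows])
      if (length(cl) != 1) {
        stop_nir("conflicting class labels for sample '%s': %s",
                 ids[i], paste(cl, collapse = ", "))
      }
      classes[i] <- cl
    }
  }
  spectrum_set(s$wavelengths, out, ids, rep("mean", length(ids)),
               class_labels = classes, instrument = s$instrument)
}

#' Align spectra with a reference chemistry table
#'
#' Matches replicate-averaged spectra with wet-chemistry records by sample
#' id. Samples present on only one side are dropped (the count is reported
#' via a message). Output row order follows sorted sample id, so alignment
#' depends only on the id sets.
#'
#' @param s a replicate-averaged [spectrum_set()].
#' @param ref data.frame with a `sample_id` column (see
#'   [sample_composition()]).
#' @return list with `X` (absorbance matrix), `Y` (aligned reference rows),
#'   `labels` (botanical classes or `NULL`), `wavelengths`, `dropped`.
#' @export
align_spectra <- function(s, ref) {
  stopifnot(inherits(s, "spectrum_set"))
  assert_that(!anyDuplicated(s$sample_ids),
              "spectra contain replicate rows; call average_replicates() first")
  assert_that("sample_id" %in% names(ref), "ref must have a sample_id column")
  common <- sort(intersect(s$sample_ids, ref$sample_id))
  if (!length(common)) stop_nir("no overlapping sample ids between spectra and reference")
  dropped <- (length(s$sample_ids) - length(common)) +
             (length(unique(ref$sample_id)) - length(common))
  if (dropped > 0) message(sprintf("align_spectra: dropped %d unmatched sample(s)", dropped))
  xi <- match(common, s$sample_ids)
  yi <- match(common, ref$sample_id)
  X <- s$absorbance[xi, , drop = FALSE]
  rownames(X) <- common
  list(X = X,
       Y = ref[yi, , drop = FALSE],
       labels = if (!is.null(s$class_labels)) s$class_labels[xi]
                else if ("botanical_class" %in% names(ref)) ref$botanical_class[yi]
                else NULL,
       wavelengths = s$wavelengths,
       dropped = dropped)
}
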