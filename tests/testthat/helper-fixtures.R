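# Shared fixture builders (everything generated in code, nothing on disk).

# Small noiseless toy instrument: 10 points, 1000-1090 nm.
toy_profile <- function(noise_sd = 0) {
  instrument_profile("toy", 1000, 1090, 10, mode = "transflectance",
                     pathlength = 1, noise_sd = noise_sd)
}

# Composition table with all analyte concentrations fixed to given values.
fixed_records <- function(n, class = "CH", moisture = 0, hmf = 0, diastase = 0,
                          conductivity = 0, glucose = 0, fructose = 0) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             botanical_class = class, moisture = moisture, hmf = hmf,
             diastase = diastase, conductivity = conductivity,
             glucose = glucose, fructose = fructose,
             reducing_sugars = glucose + fructose,
             ph = 4.5, stringsAsFactors = FALSE)
}

# Replicate-averaged benchtop glucose fixture used by selection tests.
glucose_fixture <- function(seed, profile = nir_profile("benchtop"),
                            preproc = preprocess_spec("none", FALSE, 1, 2, 0,
                                                      "mean_center")) {
  rec <- sample_composition(seed = seed)
  s <- simulate_spectra(rec, profile, replicates = 2, seed = seed + 100)
  al <- align_spectra(average_replicates(s), rec)
  X <- preprocess_fit_apply(preproc, al$X, grid_step = profile$resolution)$X_cal
  list(X = X, y = al$Y$glucose, labels = al$labels,
       wavelengths = al$wavelengths, raw = al$X)
}

# Independent per-sample counting oracle for classification metrics:
# expands labels, counts TP/FP/FN/TN one sample at a time, and computes the
# metrics straight from the printed definitions (indicator-covariance form
# for the multiclass MCC).
oracle_classification_metrics <- function(y_true, y_pred, classes) {
  n <- length(y_true)
  C <- length(classes)
  tp <- fp <- fn <- tn <- stats::setNames(numeric(C), classes)
  correct <- 0
  for (i in seq_len(n)) {
    if (y_true[i] == y_pred[i]) correct <- correct + 1
    for (cl in classes) {
      t_is <- y_true[i] == cl
      p_is <- y_pred[i] == cl
      if (t_is && p_is) tp[cl] <- tp[cl] + 1
      if (!t_is && p_is) fp[cl] <- fp[cl] + 1
      if (t_is && !p_is) fn[cl] <- fn[cl] + 1
      if (!t_is && !p_is) tn[cl] <- tn[cl] + 1
    }
  }
  recall <- tp / (tp + fn)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  # multiclass MCC via indicator covariances (reduces to the binary formula)
  Tm <- sapply(classes, function(cl) as.numeric(y_true == cl))
  Pm <- sapply(classes, function(cl) as.numeric(y_pred == cl))
  cv <- function(a, b) sum((a - mean(a)) * (b - mean(b)))
  num <- sum(vapply(seq_len(C), function(k) cv(Tm[, k], Pm[, k]), 0))
  den <- sqrt(sum(vapply(seq_len(C), function(k) cv(Tm[, k], Tm[, k]), 0)) *
              sum(vapply(seq_len(C), function(k) cv(Pm[, k], Pm[, k]), 0)))
  list(accuracy = correct / n,
       ba = mean(recall),
       f1_macro = mean(f1),
       mcc = if (den == 0) 0 else num / den)
}

# Random label pair with every class present among the true labels.
random_labels <- function(n, C) {
  classes <- LETTERS[seq_len(C)]
  repeat {
    y_true <- sample(classes, n, replace = TRUE)
    if (length(unique(y_true)) == C) break
  }
  # predictions correlate with truth so the confusion matrix is non-trivial
  y_pred <- ifelse(stats::runif(n) < 0.6, y_true, sample(classes, n, replace = TRUE))
  list(y_true = y_true, y_pred = y_pred, classes = classes)
}
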