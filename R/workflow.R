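# Workflow orchestration ----------------------------------------------------

#' Default candidate pre-processing chains
#'
#' A compact, representative slice of the full enumeration used by the
#' workflow driver: raw centred spectra, SNV, SNV + smoothing and a
#' first-derivative chain.
#'
#' @return list of [preprocess_spec()].
#' @export
default_preproc_candidates <- function() {
  list(preprocess_spec("none", FALSE, 1, 2, 0, "mean_center"),
       preprocess_spec("SNV", FALSE, 1, 2, 0, "mean_center"),
       preprocess_spec("SNV", FALSE, 9, 2, 0, "mean_center"),
       preprocess_spec("SNV", TRUE, 7, 2, 1, "mean_center"))
}

#' Default candidate models
#'
#' @param task `"regression"` or `"classification"`.
#' @param n_lv_grid latent-variable counts for the PLS candidates.
#' @param pca_components score dimensionality for the kNN/RF/SVM candidates.
#' @return list of [model_spec()].
#' @export
default_model_candidates <- function(task = c("regression", "classification"),
                                     n_lv_grid = c(2, 4, 6, 8, 10),
                                     pca_components = 8) {
  task <- match.arg(task)
  if (task == "regression") {
    c(lapply(n_lv_grid, function(a) model_spec("PLS", task, list(n_lv = a))),
      list(model_spec("SVM", task, list(kernel = "linear", cost = 1),
                      pca_components = pca_components),
           model_spec("RF", task, list(n_trees = 300, max_depth = 15),
                      pca_components = pca_components),
           model_spec("kNN", task, list(k = 5, metric = "euclidean"),
                      pca_components = pca_components)))
  } else {
    list(model_spec("SVM", task, list(kernel = "linear", cost = 1),
                    pca_components = pca_components),
         model_spec("RF", task, list(n_trees = 300, max_depth = 15),
                    pca_components = pca_components),
         model_spec("kNN", task, list(k = 5, metric = "euclidean"),
                    pca_components = pca_components))
  }
}

#' Configure a workflow run
#'
#' @param instrument profile name, see [nir_profile()].
#' @param targets response names (composition columns) and/or
#'   `"botanical_origin"` for the classification task.
#' @param band_selection `"none"`, `"siPLS"` or `"siPLS+CARS"`.
#' @param cv_scheme `"VB5"` or `"B100"`.
#' @param seed integer seed driving every stochastic stage.
#' @param n_per_class synthetic sample counts per botanical class.
#' @param replicates scans per sample.
#' @param preprocs,models candidate lists (defaults above; `models` may be
#'   `NULL` to pick the task-appropriate default set).
#' @param spectra_path,reference_path optional CSV inputs; when given, data
#'   are read instead of simulated.
#' @return object of class `workflow_config`.
#' @export
workflow_config <- function(instrument = "benchtop",
                            targets = c("glucose"),
                            band_selection = c("none", "siPLS", "siPLS+CARS"),
                            cv_scheme = c("VB5", "B100"),
                            seed = 1L,
                            n_per_class = c(CH = 30, PF = 30, MF = 18),
                            replicates = 2,
                            preprocs = default_preproc_candidates(),
                            models = NULL,
                            spectra_path = NULL, reference_path = NULL) {
  band_selection <- match.arg(band_selection)
  cv_scheme <- match.arg(cv_scheme)
  assert_that(length(targets) > 0, "targets must be non-empty")
  structure(list(instrument = instrument, targets = targets,
                 band_selection = band_selection, cv_scheme = cv_scheme,
                 seed = assert_seed(seed), n_per_class = n_per_class,
                 replicates = replicates, preprocs = preprocs,
                 models = models, spectra_path = spectra_path,
                 reference_path = reference_path),
            class = "workflow_config")
}

workflow_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run a calibration / classification workflow
#'
#' Executes the full pipeline for one instrument configuration: data
#' acquisition (synthetic simulation or CSV input) -> replicate averaging ->
#' alignment with reference chemistry -> optional wavelength selection
#' (siPLS, optionally refined by CARS-PLS) -> pre-processing x model grid
#' search per target. Wavelength selection is performed once per target on
#' the first candidate chain's pre-processed spectra, and the selected mask
#' is then applied for every grid candidate. Fully deterministic given the
#' config.
#'
#' @param cfg a [workflow_config()].
#' @param verbose log one line per stage.
#' @return list with `leaderboard` (all evaluated combinations),
#'   `best` (one row per target), `results` (named list of winning
#'   `evaluation_result`s), `selection` (per-target
#'   `band_selection_result`s or `NULL`), `data` (the aligned matrices).
#' @export
run_workflow <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "workflow_config"))
  profile <- nir_profile(cfg$instrument)

  if (!is.null(cfg$spectra_path)) {
    spectra <- read_spectra_csv(cfg$spectra_path, instrument = profile)
    assert_that(!is.null(cfg$reference_path), "reference_path required with spectra_path")
    ref <- utils::read.csv(cfg$reference_path, stringsAsFactors = FALSE)
  } else {
    ref <- sample_composition(cfg$n_per_class, seed = cfg$seed)
    spectra <- simulate_spectra(ref, profile, replicates = cfg$replicates,
                                seed = cfg$seed + 1L)
  }
  workflow_log(verbose, "data", "%d scans x %d wavelengths, %d reference rows, seed %d",
               nrow(spectra$absorbance), length(spectra$wavelengths),
               nrow(ref), cfg$seed)
  avg <- average_replicates(spectra)
  aligned <- align_spectra(avg, ref)
  workflow_log(verbose, "align", "%d aligned samples, %d dropped",
               nrow(aligned$X), aligned$dropped)

  grid_step <- profile$resolution
  leaderboard <- NULL
  best_rows <- NULL
  results <- list()
  selection <- list()

  for (target in cfg$targets) {
    classify <- identical(target, "botanical_origin")
    y <- if (classify) aligned$labels else aligned$Y[[target]]
    assert_that(!is.null(y), "unknown target '%s'", target)
    task <- if (classify) "classification" else "regression"
    models <- cfg$models %||% default_model_candidates(task)
    X <- aligned$X
    n_vars <- ncol(X)
    sel <- NULL

    if (cfg$band_selection != "none" && !classify) {
      prep0 <- preprocess_fit_apply(cfg$preprocs[[1]], X, grid_step = grid_step)
      Xp <- prep0$X_cal
      folds <- venetian_blind_folds(nrow(Xp), 5)
      amax <- min(10, nrow(Xp) - 2, ncol(Xp))
      m0 <- fit_pls(Xp, y, amax)
      diag <- list(vip = vip(m0), sr = selectivity_ratio(m0, Xp))
      iv <- candidate_intervals(diag)
      sel <- sipls_search(iv, Xp, y, folds, max_n_lv = amax)
      if (cfg$band_selection == "siPLS+CARS" &&
          length(sel$selected_indices) > 30) {
        cars <- cars_pls(Xp[, sel$selected_indices, drop = FALSE], y, folds,
                         max_n_lv = amax, seed = cfg$seed + 2L)
        sel$selected_indices <- sel$selected_indices[cars$selected_indices]
        sel$method <- "siPLS+CARS"
        sel$cars <- cars
      }
      X <- X[, sel$selected_indices, drop = FALSE]
      n_vars <- ncol(X)
      workflow_log(verbose, "select", "%s kept %d / %d wavelengths for %s",
                   sel$method, n_vars, ncol(aligned$X), target)
    }
    selection[[target]] <- sel

    gs <- grid_search(task, cfg$preprocs, models, X, y,
                      cv_scheme = cfg$cv_scheme, seed = cfg$seed,
                      grid_step = grid_step)
    lb <- gs$leaderboard
    lb$target <- target
    lb$band_selected <- !is.null(sel)
    lb$n_vars <- n_vars
    leaderboard <- rbind_fill(leaderboard, lb)
    best_rows <- rbind_fill(best_rows,
                            eval_to_row(gs$best, target, !is.null(sel), n_vars))
    results[[target]] <- gs$best
    workflow_log(verbose, "grid", "%s: best %s | %s", target,
                 gs$best$model_id, gs$best$preproc_id)
  }
  list(leaderboard = leaderboard, best = best_rows, results = results,
       selection = selection,
       data = aligned, config = cfg)
}

#' Compare full-spectrum and band-selected workflow runs
#'
#' Per shared target: difference in headline metric (R2 for regression, BA
#' for classification), difference in variable count (parsimony), and a
#' status flag with a +/- `margin` neutrality band.
#'
#' @param lb_full,lb_selected `best` data.frames from [run_workflow()].
#' @param margin neutrality margin on the metric delta.
#' @return data.frame, one row per target.
#' @export
compare_workflows <- function(lb_full, lb_selected, margin = 0.02) {
  assert_that(setequal(lb_full$target, lb_selected$target),
              "the two leaderboards must cover the same targets")
  out <- NULL
  for (tg in lb_full$target) {
    a <- lb_full[lb_full$target == tg, ]
    b <- lb_selected[lb_selected$target == tg, ]
    metric <- if ("r2" %in% names(a) && !is.na(a$r2[1])) "r2" else "ba"
    delta <- b[[metric]][1] - a[[metric]][1]
    status <- if (delta > margin) "improvement"
              else if (delta < -margin) "degradation" else "neutral"
    out <- rbind(out, data.frame(target = tg, metric = metric,
                                 delta = delta,
                                 delta_n_vars = b$n_vars[1] - a$n_vars[1],
                                 status = status,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Composition table with one-way ANOVA per trait
#'
#' Compares the CH and PF groups trait by trait: group means, pooled SEM
#' (`sqrt(MSE / n)` with n the per-group size), the one-way ANOVA F-test
#' p-value and a Shapiro-Wilk normality p-value on the residuals (reported,
#' not gating). MF rows are excluded before testing — a pooled multifloral
#' class is not a compositionally homogeneous group.
#'
#' @param ref composition data.frame from [sample_composition()] (or read
#'   from CSV).
#' @param groups the two classes compared.
#' @param traits trait columns to test.
#' @return data.frame shaped like a composition summary table: one row per
#'   trait with group means, `p_value` and `sem`.
#' @export
composition_anova <- function(ref, groups = c("CH", "PF"),
                              traits = c("moisture", "hmf", "diastase",
                                         "conductivity", "glucose",
                                         "fructose", "reducing_sugars", "ph")) {
  keep <- ref$botanical_class %in% groups
  df <- ref[keep, , drop = FALSE]
  counts <- table(df$botanical_class)
  assert_that(all(groups %in% names(counts)) && all(counts[groups] >= 2),
              "each group needs at least 2 samples")
  out <- NULL
  for (tr in traits) {
    assert_that(tr %in% names(df), "unknown trait '%s'", tr)
    y <- df[[tr]]
    g <- factor(df$botanical_class, levels = groups)
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    mse <- an["Residuals", "Mean Sq"]
    pval <- an[1, "Pr(>F)"]
    if (stats::var(y) == 0) pval <- 1     # identical groups: F = 0 region
    means <- tapply(y, g, mean)
    sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) NA_real_)
    row <- data.frame(trait = tr, t(means),
                      p_value = pval,
                      sem = sqrt(mse / mean(counts[groups])),
                      shapiro_p = sw,
                      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  names(out)[2:3] <- groups
  out
}

#' Render results as report tables
#'
#' Formats leaderboard rows into the conventional reporting layout:
#' regression rows (Model, Pre-Processing, CV Scheme, R2, RMSE, MAE) and
#' classification rows (.., Accuracy, BA, F1-Score, MCC), metrics to 2
#' decimals; composition rows get p-values to 3 decimals. Returns the
#' tables plus a markdown rendering.
#'
#' @param results list with any of `best`/`leaderboard` (from
#'   [run_workflow()]) and `composition` (from [composition_anova()]).
#' @return list with `regression`, `classification`, `composition`
#'   data.frames (when present) and `markdown` (character vector).
#' @export
render_reports <- function(results) {
  assert_that(length(results) > 0, "results must be non-empty")
  out <- list()
  md <- character()
  lb <- results$best %||% results$leaderboard
  if (!is.null(lb)) {
    fmt2 <- function(x) sprintf("%.2f", x)
    if ("r2" %in% names(lb) && any(!is.na(lb$r2))) {
      reg <- lb[!is.na(lb$r2), ]
      out$regression <- data.frame(Target = reg$target, Model = reg$model,
                                   `Pre-Processing` = reg$preprocessing,
                                   `CV Scheme` = reg$cv_scheme,
                                   R2 = fmt2(reg$r2), RMSE = fmt2(reg$rmse),
                                   MAE = fmt2(reg$mae), check.names = FALSE)
      md <- c(md, "## Regression performance", df_to_markdown(out$regression))
    }
    if ("ba" %in% names(lb) && any(!is.na(lb$ba))) {
      cls <- lb[!is.na(lb$ba), ]
      out$classification <- data.frame(Target = cls$target, Model = cls$model,
                                       `Pre-Processing` = cls$preprocessing,
                                       `CV Scheme` = cls$cv_scheme,
                                       Accuracy = fmt2(cls$accuracy),
                                       BA = fmt2(cls$ba),
                                       `F1-Score` = fmt2(cls$f1_macro),
                                       MCC = fmt2(cls$mcc), check.names = FALSE)
      md <- c(md, "## Classification performance",
              df_to_markdown(out$classification))
    }
  }
  if (!is.null(results$composition)) {
    comp <- results$composition
    cols <- setdiff(names(comp), c("trait", "p_value", "shapiro_p"))
    tab <- data.frame(Variable = comp$trait)
    for (cl in cols) tab[[cl]] <- sprintf("%.2f", comp[[cl]])
    tab[["p-Value"]] <- sprintf("%.3f", comp$p_value)
    out$composition <- tab
    md <- c(md, "## Composition by botanical origin", df_to_markdown(tab))
  }
  out$markdown <- md
  out
}

df_to_markdown <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows, "")
}
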