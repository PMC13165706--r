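# align columns of two best-row tables with different metric blocks
rbind_fill_test <- function(a, b) {
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[, names(a)])
}

small_cfg <- function(seed = 3, band = "none", targets = "glucose") {
  workflow_config("narrow_portable", targets = targets,
                  band_selection = band, seed = seed,
                  n_per_class = c(CH = 10, PF = 10, MF = 5),
                  preprocs = default_preproc_candidates()[1:2],
                  models = if (identical(targets, "botanical_origin")) {
                    list(model_spec("SVM", "classification",
                                    list(kernel = "linear", cost = 1),
                                    pca_components = 4))
                  } else {
                    list(model_spec("PLS", "regression", list(n_lv = 3)),
                         model_spec("PLS", "regression", list(n_lv = 6)))
                  })
}

test_that("workflow reruns are byte-identical for a fixed config", {
  suppressMessages({
    wf1 <- run_workflow(small_cfg())
    wf2 <- run_workflow(small_cfg())
  })
  expect_identical(wf1$leaderboard, wf2$leaderboard)
  expect_identical(wf1$best, wf2$best)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(wf1$leaderboard, f1, row.names = FALSE)
  write.csv(wf2$leaderboard, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("band-selected runs use a strict subset of wavelengths", {
  suppressMessages({
    wf_full <- run_workflow(small_cfg(band = "none"))
    wf_sel <- run_workflow(small_cfg(band = "siPLS"))
  })
  expect_lt(wf_sel$best$n_vars[1], wf_full$best$n_vars[1])
  expect_false(is.null(wf_sel$selection$glucose))
  cmp <- compare_workflows(wf_full$best, wf_sel$best)
  expect_identical(cmp$target, "glucose")
  expect_lt(cmp$delta_n_vars, 0)
  expect_equal(cmp$delta,
               wf_sel$best$r2[1] - wf_full$best$r2[1], tolerance = 1e-12)
})

test_that("classification targets flow through the workflow", {
  suppressMessages(wf <- run_workflow(small_cfg(targets = "botanical_origin")))
  expect_true("ba" %in% names(wf$best))
  expect_gte(wf$best$ba[1], 0)
  expect_lte(wf$best$ba[1], 1)
})

test_that("identical leaderboards compare as neutral", {
  suppressMessages(wf <- run_workflow(small_cfg()))
  cmp <- compare_workflows(wf$best, wf$best)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$delta_n_vars, 0)
  expect_identical(cmp$status, "neutral")
  other <- wf$best; other$target <- "moisture"
  expect_error(compare_workflows(wf$best, other), "same targets")
})

test_that("two-group ANOVA reduces to the pooled t-test", {
  rec <- sample_composition(c(CH = 30, PF = 30), seed = 2)
  rep <- composition_anova(rec)
  expect_identical(rep$trait,
                   c("moisture", "hmf", "diastase", "conductivity", "glucose",
                     "fructose", "reducing_sugars", "ph"))
  for (tr in c("glucose", "moisture")) {
    tt <- t.test(rec[[tr]] ~ rec$botanical_class, var.equal = TRUE)
    expect_equal(rep$p_value[rep$trait == tr], tt$p.value, tolerance = 1e-10)
  }
  # one strongly separated trait is significant on a 30+30 draw
  expect_lt(rep$p_value[rep$trait == "glucose"], 0.05)
  expect_true(all(rep$sem > 0))
})

test_that("identical groups give equal means and a null F test", {
  rec <- fixed_records(10, class = "CH", glucose = 20, fructose = 38,
                       moisture = 17)
  rec2 <- rec
  rec2$botanical_class <- "PF"
  rec2$sample_id <- paste0("p", rec2$sample_id)
  both <- rbind(rec, rec2)
  rep <- composition_anova(both, traits = "glucose")
  expect_equal(rep$CH, rep$PF)
  expect_equal(rep$p_value, 1)
  expect_error(composition_anova(rec[1, ], traits = "glucose"), "at least 2")
})

test_that("multifloral rows are excluded from the composition ANOVA", {
  rec <- sample_composition(c(CH = 15, PF = 15, MF = 40), seed = 4)
  rep_all <- composition_anova(rec)
  rep_chpf <- composition_anova(rec[rec$botanical_class != "MF", ])
  expect_equal(rep_all, rep_chpf)
})

test_that("reports are partitioned into regression and classification tables", {
  suppressMessages({
    wf_r <- run_workflow(small_cfg())
    wf_c <- run_workflow(small_cfg(targets = "botanical_origin"))
  })
  mixed <- list(best = rbind_fill_test(wf_r$best, wf_c$best),
                composition = composition_anova(sample_composition(
                  c(CH = 10, PF = 10), seed = 1)))
  rep <- render_reports(mixed)
  expect_identical(names(rep$regression),
                   c("Target", "Model", "Pre-Processing", "CV Scheme",
                     "R2", "RMSE", "MAE"))
  expect_identical(names(rep$classification),
                   c("Target", "Model", "Pre-Processing", "CV Scheme",
                     "Accuracy", "BA", "F1-Score", "MCC"))
  expect_equal(nrow(rep$regression), 1L)
  expect_equal(nrow(rep$classification), 1L)
  expect_true(all(grepl("^\\d+\\.\\d{3}$", rep$composition[["p-Value"]])))
  expect_gt(length(rep$markdown), 5)
})
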