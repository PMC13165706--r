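test_that("SNV standardises rows with the sample SD and is idempotent", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(1)
  X <- matrix(rnorm(60, 5, 3), 5, 12)
  Z <- snv(X)
  expect_equal(unname(rowMeans(Z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(Z), Z, tolerance = 1e-12)
  expect_error(snv(rbind(X, 7)), "zero-variance")
})

test_that("MSC removes affine scatter relative to the reference", {
  set.seed(2)
  ref <- sin(seq(0, 3, length.out = 20)) + 2
  X <- rbind(ref, ref, ref)
  out <- msc(X)
  expect_equal(unname(out$X), unname(X), tolerance = 1e-10)   # a=0, b=1
  expect_equal(out$reference, unname(ref))

  X2 <- rbind(2 * ref + 5, 0.5 * ref - 1)
  out2 <- msc(X2, reference = ref)
  expect_equal(unname(out2$X[1, ]), unname(ref), tolerance = 1e-10)
  expect_equal(unname(out2$X[2, ]), unname(ref), tolerance = 1e-10)

  # validation rows corrected against the calibration reference differ from
  # self-referenced correction
  val <- matrix(ref + rnorm(20, 0, 0.3), 2, 20, byrow = TRUE) + c(0, 1)
  against_cal <- msc(val, reference = ref)$X
  self_ref <- msc(val)$X
  expect_false(isTRUE(all.equal(against_cal, self_ref)))
})

test_that("detrending removes straight lines and is idempotent", {
  line <- matrix(3 * (1:10) + 7, 1)
  expect_equal(detrend_linear(line), matrix(0, 1, 10), tolerance = 1e-10)

  quad <- matrix(c(0, 1, 4, 9, 16), 1)
  # independent oracle: residuals of lm on the index
  expected <- unname(resid(lm(c(0, 1, 4, 9, 16) ~ seq_len(5))))
  expect_equal(unname(detrend_linear(quad)[1, ]), expected, tolerance = 1e-10)
  expect_equal(sum(detrend_linear(quad)), 0, tolerance = 1e-10)
  expect_equal(detrend_linear(detrend_linear(quad)), detrend_linear(quad),
               tolerance = 1e-10)
})

test_that("Savitzky-Golay differentiates polynomials exactly, edges included", {
  lam <- seq(900, 1100, by = 2)
  X <- rbind(3 * lam + 2, 5 * lam - 1)
  d1 <- savitzky_golay(X, window = 7, polyorder = 2, deriv = 1, grid_step = 2)
  expect_equal(unname(d1[1, ]), rep(3, length(lam)), tolerance = 1e-8)
  expect_equal(unname(d1[2, ]), rep(5, length(lam)), tolerance = 1e-8)

  Xq <- matrix(lam^2, 1)
  d2 <- savitzky_golay(Xq, window = 7, polyorder = 2, deriv = 2, grid_step = 2)
  expect_equal(unname(d2[1, ]), rep(2, length(lam)), tolerance = 1e-8)

  const <- matrix(4, 1, 30)
  expect_equal(savitzky_golay(const, 9, 2, 0), const, tolerance = 1e-10)
  expect_identical(savitzky_golay(Xq, 1, 2, 0), Xq)    # window 1 = identity

  expect_error(savitzky_golay(Xq, 8, 2, 0), "odd")
  expect_error(savitzky_golay(Xq, 3, 3, 0), "exceed polyorder")
  expect_error(savitzky_golay(Xq, 7, 2, 3), "deriv")
  expect_error(preprocess_spec(sg_window = 1, sg_deriv = 1), "implies")
})

test_that("fitted chains apply calibration statistics to validation rows", {
  set.seed(3)
  Xc <- matrix(rnorm(200, 1, 0.5), 10, 20)
  Xv <- matrix(rnorm(100, 2, 0.8), 5, 20)

  ident <- preprocess_spec("none", FALSE, 1, 2, 0, "none")
  out <- preprocess_fit_apply(ident, Xc, Xv)
  expect_identical(out$X_cal, Xc)
  expect_identical(out$X_val, Xv)

  auto <- preprocess_spec("none", FALSE, 1, 2, 0, "autoscale")
  out <- preprocess_fit_apply(auto, Xc, Xv)
  expect_equal(unname(colMeans(out$X_cal)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(out$X_cal, 2, sd)), rep(1, 20), tolerance = 1e-12)
  expect_gt(max(abs(colMeans(out$X_val))), 0.1)   # validation not re-centred

  # chain equals composition of the standalone operators
  chain <- preprocess_spec("SNV", FALSE, 7, 2, 1, "none")
  out <- preprocess_fit_apply(chain, Xc, grid_step = 2)
  manual <- savitzky_golay(snv(Xc), 7, 2, 1, grid_step = 2)
  expect_equal(out$X_cal, manual, tolerance = 1e-12)

  # MSC reference comes from calibration only
  mscspec <- preprocess_spec("MSC", FALSE, 1, 2, 0, "none")
  out <- preprocess_fit_apply(mscspec, Xc, Xv)
  expect_equal(out$fitted$msc_reference, colMeans(Xc))
  expect_equal(out$X_val, msc(Xv, reference = colMeans(Xc))$X)
})

test_that("calibration transform never reads validation rows", {
  set.seed(4)
  Xc <- matrix(rnorm(200), 10, 20)
  Xv1 <- matrix(rnorm(100), 5, 20)
  Xv2 <- Xv1 + 100   # grossly perturbed validation set
  for (spec in list(preprocess_spec("MSC", TRUE, 5, 2, 0, "autoscale"),
                    preprocess_spec("SNV", FALSE, 1, 2, 0, "mean_center"))) {
    a <- preprocess_fit_apply(spec, Xc, Xv1)
    b <- preprocess_fit_apply(spec, Xc, Xv2)
    expect_identical(a$X_cal, b$X_cal)
    expect_identical(a$fitted$column_means, b$fitted$column_means)
  }
})

test_that("the pre-processing grid enumerates the full chain space", {
  grid <- enumerate_preprocess_grid()
  # independent closed-form count: 3 scatter x 2 detrend x SG combos x 3 scalings
  sg_combos <- 1   # no filtering
  for (w in seq(3, 21, 2)) for (po in 2:3) for (d in 0:2) {
    if (w > po) sg_combos <- sg_combos + 1
  }
  expect_equal(length(grid), 3 * 2 * sg_combos * 3)
  expect_equal(length(grid), 1044L)

  ids <- vapply(grid, preprocess_id, "")
  expect_false(any(duplicated(ids)))

  snv_only <- enumerate_preprocess_grid(scatter = "SNV")
  expect_true(all(vapply(snv_only, function(s) s$scatter, "") == "SNV"))
})

test_that("chain ids follow the conventional reporting notation", {
  spec <- preprocess_spec("SNV", TRUE, 9, 2, 0, "autoscale")
  expect_identical(preprocess_id(spec),
                   "SNV + linear detrending + SG (9,2) smoothing + mean centring + scaling")
  expect_identical(preprocess_id(preprocess_spec()),
                   "no Savitzky-Golay filtering")
})
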