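# Synthetic spectra generator -----------------------------------------------

#' Generator constants for spectrum simulation
#'
#' One config block holding everything the Beer-Lambert-style simulator
#' needs beyond the band truths: the linear baseline, per-class baseline
#' offsets that enforce the observed mean-absorbance ordering PF > MF > CH,
#' the multiplicative scatter SD, and the noise inflation factor applied
#' where a saturating detector exceeds its absorbance threshold.
#'
#' @param baseline_intercept,baseline_slope baseline absorbance
#'   `a + b * lambda` (slope per nm).
#' @param class_offsets named additive baseline offsets per botanical class.
#' @param scatter_sd SD of the per-scan multiplicative scatter factor
#'   (Normal with mean 1).
#' @param saturation_inflation factor multiplying `noise_sd` at grid points
#'   whose clean absorbance exceeds the profile's saturation threshold.
#' @return list of generator constants.
#' @export
sim_config <- function(baseline_intercept = 0.15, baseline_slope = 5e-5,
                       class_offsets = c(CH = 0, MF = 0.09, PF = 0.18),
                       scatter_sd = 0.02, saturation_inflation = 5) {
  list(baseline_intercept = baseline_intercept,
       baseline_slope = baseline_slope,
       class_offsets = class_offsets,
       scatter_sd = scatter_sd,
       saturation_inflation = saturation_inflation)
}

# analyte name -> composition column ("mineral" rides on conductivity)
analyte_column <- function(analyte) {
  if (analyte == "mineral") "conductivity" else analyte
}

#' Simulate NIR spectra for composition records
#'
#' Clean absorbance is the Beer-Lambert sum of Gaussian analyte bands scaled
#' by concentration and effective pathlength, plus a linear instrument
#' baseline and a class-dependent offset. Each replicate scan draws an
#' independent scatter factor `Normal(1, scatter_sd)` — effective-pathlength
#' variation — that multiplies the analyte absorption term (the baseline is
#' an instrument property and is not scattered), and adds
#' `Normal(0, noise_sd)` detector noise; for saturating instruments the
#' noise SD is inflated wherever clean absorbance exceeds the profile
#' threshold, emulating the high-absorbance noise artefact of long-path
#' transmittance cells.
#'
#' @param records data.frame from [sample_composition()].
#' @param profile an [instrument_profile()].
#' @param truths list of [band_truth()] objects; default
#'   [default_band_truths()].
#' @param replicates scans per sample (>= 1; duplicate-aliquot acquisition
#'   uses 2).
#' @param seed integer seed.
#' @param config generator constants, see [sim_config()].
#' @return a [spectrum_set()] with `replicates * nrow(records)` rows.
#' @export
simulate_spectra <- function(records, profile, truths = default_band_truths(),
                             replicates = 2, seed, config = sim_config()) {
  seed <- assert_seed(seed)
  stopifnot(inherits(profile, "instrument_profile"))
  assert_that(replicates >= 1, "replicates must be >= 1")
  grid <- profile_grid(profile)
  assert_that(length(grid) > 0, "profile wavelength grid is empty")
  if (inherits(truths, "band_truth")) truths <- list(truths)

  # p x n_analyte band shape matrix
  G <- vapply(truths, function(tr) {
    g <- numeric(length(grid))
    for (i in seq_along(tr$centers)) {
      g <- g + tr$amplitudes[i] *
        exp(-(grid - tr$centers[i])^2 / (2 * tr$sigmas[i]^2))
    }
    g
  }, numeric(length(grid)))
  analytes <- vapply(truths, `[[`, "", "analyte")
  cols <- vapply(analytes, analyte_column, "")
  missing_cols <- setdiff(cols, names(records))
  assert_that(length(missing_cols) == 0,
              "records lack columns for analytes: %s",
              paste(missing_cols, collapse = ", "))
  conc <- as.matrix(records[, cols, drop = FALSE])
  assert_that(all(conc >= 0), "negative concentrations are not allowed")

  baseline <- config$baseline_intercept + config$baseline_slope * grid
  offs <- config$class_offsets[records$botanical_class]
  offs[is.na(offs)] <- 0
  band <- conc %*% t(G) * profile$pathlength          # n x p analyte term
  additive <- matrix(baseline, nrow(conc), length(grid), byrow = TRUE) + offs
  clean <- band + additive

  noise_sd <- matrix(profile$noise_sd, nrow(conc), length(grid))
  if (is.finite(profile$saturation_threshold)) {
    noise_sd[clean > profile$saturation_threshold] <-
      profile$noise_sd * config$saturation_inflation
  }

  withr::with_seed(seed, {
    n <- nrow(conc)
    rows <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      scatter <- stats::rnorm(n, 1, config$scatter_sd)
      rows[[r]] <- band * scatter + additive +
        matrix(stats::rnorm(n * length(grid)), n) * noise_sd
    }
    absorb <- do.call(rbind, rows)
    spectrum_set(grid, absorb,
                 sample_ids = rep(records$sample_id, replicates),
                 replicate_ids = rep(sprintf("r%d", seq_len(replicates)), each = n),
                 class_labels = rep(records$botanical_class, replicates),
                 instrument = profile)
  })
}
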