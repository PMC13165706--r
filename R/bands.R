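# Absorption-band ground truth ----------------------------------------------

#' Define the absorption bands of one analyte
#'
#' Each analyte contributes a sum of Gaussian bands to the simulated
#' absorbance, `amplitude * exp(-(lambda - center)^2 / (2 sigma^2))` per unit
#' concentration. The set of grid points within two sigmas of any band center
#' is the analyte's informative wavelength set, used by selection-recovery
#' checks.
#'
#' @param analyte analyte name (must match a composition column; `"mineral"`
#'   maps to electrical conductivity).
#' @param centers band centers, nm, within 850-2500.
#' @param sigmas Gaussian band widths, nm.
#' @param amplitudes absorbance per unit concentration, non-negative.
#' @return object of class `band_truth`.
#' @export
band_truth <- function(analyte, centers, sigmas, amplitudes) {
  assert_that(length(centers) == length(sigmas) &&
              length(centers) == length(amplitudes),
              "centers, sigmas and amplitudes must have equal length")
  assert_that(all(centers >= 850 & centers <= 2500),
              "band centers must lie within 850-2500 nm")
  assert_that(all(sigmas > 0), "band sigmas must be positive")
  assert_that(all(amplitudes >= 0), "band amplitudes must be non-negative")
  structure(list(analyte = analyte, centers = centers, sigmas = sigmas,
                 amplitudes = amplitudes), class = "band_truth")
}

#' Default spectral band truths for honey constituents
#'
#' Encodes the dominant honey NIR phenomenology: water/carbohydrate O-H and
#' C-H bands at 1420-1470 nm and 1900-1940 nm and the C-H combination-band
#' region at 2050-2150 nm. Moisture carries the two water bands; glucose
#' carries the carbohydrate C-H combination band centred at 2100 nm (its
#' two-sigma informative set is exactly 2050-2150 nm); fructose carries a
#' first-overtone band at 1460 nm plus a well-separated combination band at
#' 2270 nm, so the sugar bands are mutually identifiable; HMF gets a single
#' tiny-amplitude band at 2150 nm and diastatic activity gets no band at
#' all, so both are poorly predictable by construction; the mineral latent
#' (electrical conductivity) carries one weak, very broad band.
#'
#' @return list of [band_truth()] objects.
#' @export
default_band_truths <- function() {
  list(
    band_truth("moisture", centers = c(1440, 1920), sigmas = c(20, 15),
               amplitudes = c(0.020, 0.024)),
    band_truth("glucose",  centers = 2100, sigmas = 25, amplitudes = 0.012),
    band_truth("fructose", centers = c(1460, 2270), sigmas = c(15, 30),
               amplitudes = c(0.012, 0.009)),
    band_truth("hmf",      centers = 2150, sigmas = 10, amplitudes = 1e-4),
    band_truth("mineral",  centers = 1700, sigmas = 200, amplitudes = 0.002)
  )
}

#' Informative wavelength mask
#'
#' Marks the grid points lying within two sigmas of any band center of any
#' analyte with positive amplitude — the ground-truth informative set that
#' band-selection procedures are expected to recover.
#'
#' @param truths list of [band_truth()] objects (non-empty).
#' @param profile an [instrument_profile()].
#' @return logical vector over [profile_grid()].
#' @export
informative_mask <- function(truths, profile) {
  assert_that(length(truths) > 0, "truths must be non-empty")
  if (inherits(truths, "band_truth")) truths <- list(truths)
  grid <- profile_grid(profile)
  mask <- rep(FALSE, length(grid))
  for (tr in truths) {
    keep <- tr$amplitudes > 0
    for (i in which(keep)) {
      mask <- mask | (abs(grid - tr$centers[i]) <= 2 * tr$sigmas[i])
    }
  }
  mask
}
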