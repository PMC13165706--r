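# Instrument profiles -------------------------------------------------------

#' Create an NIR instrument profile
#'
#' A profile describes the wavelength grid and acquisition characteristics of
#' one analytical configuration: range, resolution, acquisition mode,
#' effective optical pathlength, baseline additive noise and (optionally) the
#' absorbance level above which the detector response degrades and noise is
#' inflated.
#'
#' @param name profile name.
#' @param lambda_min,lambda_max wavelength range in nm.
#' @param resolution grid step in nm.
#' @param mode acquisition geometry, `"transflectance"` or `"transmittance"`.
#' @param pathlength effective optical pathlength multiplier applied to the
#'   analyte absorption term (arbitrary units; 1 = reference path).
#' @param noise_sd standard deviation of additive detector noise, absorbance
#'   units.
#' @param saturation_threshold absorbance above which noise is inflated
#'   (`NA` for a detector without a saturation artefact).
#' @return an object of class `instrument_profile`.
#' @export
instrument_profile <- function(name, lambda_min, lambda_max, resolution,
                               mode = c("transflectance", "transmittance"),
                               pathlength = 1, noise_sd = 0.005,
                               saturation_threshold = NA_real_) {
  mode <- match.arg(mode)
  assert_that(lambda_min < lambda_max, "lambda_min must be below lambda_max")
  assert_that(resolution > 0, "resolution must be positive")
  assert_that(pathlength > 0, "pathlength must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(name = name,
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 resolution = resolution, mode = mode,
                 pathlength = pathlength, noise_sd = noise_sd,
                 saturation_threshold = saturation_threshold),
            class = "instrument_profile")
}

#' Wavelength grid of a profile
#'
#' Arithmetic sequence from `lambda_min` stepping by `resolution`, never
#' exceeding `lambda_max`.
#'
#' @param profile an [instrument_profile()].
#' @return numeric vector of wavelengths in nm.
#' @export
profile_grid <- function(profile) {
  stopifnot(inherits(profile, "instrument_profile"))
  seq(profile$lambda_min, profile$lambda_max, by = profile$resolution)
}

#' Built-in instrument profiles
#'
#' Three analytical configurations studied for honey: a benchtop scanning
#' monochromator (850-2500 nm at 0.5 nm, transflectance), a portable
#' wide-range spectrometer (1350-2500 nm at 16 nm, transflectance) and a
#' portable narrow-range transmittance instrument (1102-1600 nm at 2 nm)
#' whose long cuvette path drives absorbance above 2 in the strong
#' water/sugar band region, with visibly inflated noise there.
#'
#' @param name one of `"benchtop"`, `"wide_portable"`, `"narrow_portable"`.
#' @return an [instrument_profile()].
#' @export
nir_profile <- function(name = c("benchtop", "wide_portable", "narrow_portable")) {
  name <- match.arg(name)
  switch(name,
    benchtop = instrument_profile("benchtop", 850, 2500, 0.5,
                                  mode = "transflectance", pathlength = 1,
                                  noise_sd = 0.005),
    wide_portable = instrument_profile("wide_portable", 1350, 2500, 16,
                                       mode = "transflectance", pathlength = 1,
                                       noise_sd = 0.02),
    narrow_portable = instrument_profile("narrow_portable", 1102, 1600, 2,
                                         mode = "transmittance", pathlength = 3,
                                         noise_sd = 0.01,
                                         saturation_threshold = 2))
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf("<instrument_profile> %s: %g-%g nm @ %g nm (%s), path %g, noise sd %g\n",
              x$name, x$lambda_min, x$lambda_max, x$resolution, x$mode,
              x$pathlength, x$noise_sd))
  invisible(x)
}
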