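# Reference chemistry generator ---------------------------------------------

#' Class-wise composition parameters
#'
#' Per-class means and standard deviations of the eight wet-chemistry traits
#' for chestnut (CH) and polyfloral (PF) honey, on the usual reporting
#' scales. Standard deviations are reconstructed from the per-variable
#' standard error of the mean at a group size of 30 (SD = SEM * sqrt(30)).
#' Reducing sugars are not parameterised: they are the exact sum of glucose
#' and fructose. pH is a deterministic line in electrical conductivity
#' through the two class means (both reflect mineral/organic-acid content,
#' not a dedicated NIR chromophore). The pooled multifloral class (MF) is a
#' 50/50 mixture of the CH and PF parameter sets with 1.5x inflated SDs.
#'
#' @return nested list: `$classes$CH`, `$classes$PF` (each a data.frame with
#'   `mean` and `sd` per trait), `$mf_sd_inflation`, `$ph_intercept`,
#'   `$ph_slope`, `$bounds`.
#' @export
composition_params <- function() {
  sem <- c(moisture = 0.18, hmf = 1.01, diastase = 1.39, conductivity = 0.06,
           glucose = 0.46, fructose = 0.51)
  sd <- sem * sqrt(30)
  ch <- data.frame(mean = c(moisture = 17.1, hmf = 5.87, diastase = 29.3,
                            conductivity = 1.92, glucose = 20.4, fructose = 38.5),
                   sd = sd)
  pf <- data.frame(mean = c(moisture = 17.7, hmf = 12.7, diastase = 26.9,
                            conductivity = 0.79, glucose = 30.2, fructose = 38.4),
                   sd = sd)
  ph_slope <- (5.11 - 4.10) / (1.92 - 0.79)
  list(classes = list(CH = ch, PF = pf),
       mf_sd_inflation = 1.5,
       ph_intercept = 5.11 - ph_slope * 1.92,
       ph_slope = ph_slope,
       bounds = list(moisture = c(13, 25)))
}

trait_names <- c("moisture", "hmf", "diastase", "conductivity",
                 "glucose", "fructose")

draw_class_records <- function(n, par, params) {
  out <- matrix(NA_real_, n, length(trait_names),
                dimnames = list(NULL, trait_names))
  for (tr in trait_names) {
    b <- params$bounds[[tr]]
    lo <- if (is.null(b)) 0 else b[1]
    hi <- if (is.null(b)) Inf else b[2]
    out[, tr] <- rtrunc_norm(n, par[tr, "mean"], par[tr, "sd"], lo, hi)
  }
  out
}

#' Sample honey composition records
#'
#' Draws per-sample wet-chemistry values from truncated normal distributions
#' parameterised by [composition_params()]. Within every record, reducing
#' sugars equal glucose plus fructose exactly, and pH is the fixed linear
#' function of electrical conductivity. MF records straddle the CH and PF
#' parameter sets: each MF sample draws its parameters from one of the two
#' classes at random, with inflated spread.
#'
#' @param n_per_class named integer vector of class sizes, names among
#'   `"CH"`, `"PF"`, `"MF"`; default 30/30/18.
#' @param seed integer seed; all randomness is local to this call.
#' @param params parameter set, defaults to [composition_params()].
#' @return data.frame with columns `sample_id`, `botanical_class`, the six
#'   drawn traits, `reducing_sugars` and `ph`.
#' @export
sample_composition <- function(n_per_class = c(CH = 30, PF = 30, MF = 18),
                               seed, params = composition_params()) {
  seed <- assert_seed(seed)
  valid <- c("CH", "PF", "MF")
  assert_that(length(n_per_class) > 0 && !is.null(names(n_per_class)),
              "n_per_class must be a named vector")
  bad <- setdiff(names(n_per_class), valid)
  if (length(bad)) {
    stop_nir("unknown class name(s): %s; valid classes are %s",
             paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  }
  assert_that(all(n_per_class >= 1), "n_per_class entries must be >= 1")

  withr::with_seed(seed, {
    blocks <- lapply(names(n_per_class), function(cl) {
      n <- n_per_class[[cl]]
      if (cl == "MF") {
        pick <- sample(c("CH", "PF"), n, replace = TRUE)
        vals <- matrix(NA_real_, n, length(trait_names),
                       dimnames = list(NULL, trait_names))
        for (src in c("CH", "PF")) {
          idx <- which(pick == src)
          if (!length(idx)) next
          par <- params$classes[[src]]
          par$sd <- par$sd * params$mf_sd_inflation
          vals[idx, ] <- draw_class_records(length(idx), par, params)
        }
      } else {
        vals <- draw_class_records(n, params$classes[[cl]], params)
      }
      df <- as.data.frame(vals)
      df$botanical_class <- cl
      df
    })
    out <- do.call(rbind, blocks)
    out$reducing_sugars <- out$glucose + out$fructose
    out$ph <- params$ph_intercept + params$ph_slope * out$conductivity
    out$sample_id <- sprintf("%s_%03d", out$botanical_class,
                             stats::ave(seq_len(nrow(out)), out$botanical_class,
                                        FUN = seq_along))
    out[, c("sample_id", "botanical_class", "moisture", "hmf", "diastase",
            "conductivity", "glucose", "fructose", "reducing_sugars", "ph")]
  })
}
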