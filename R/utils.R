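#' @keywords internal
"_PACKAGE"

# Internal assertion helpers ------------------------------------------------

stop_nir <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_nir(...)
  invisible(TRUE)
}

assert_matrix <- function(X, name = "X", min_cols = 1L) {
  assert_that(is.matrix(X) && is.numeric(X), "%s must be a numeric matrix", name)
  assert_that(all(is.finite(X)), "%s contains non-finite values", name)
  assert_that(ncol(X) >= min_cols, "%s needs at least %d columns", name, min_cols)
  invisible(TRUE)
}

assert_seed <- function(seed) {
  assert_that(length(seed) == 1L && is.finite(seed) && seed == round(seed),
              "seed must be a single integer")
  invisible(as.integer(seed))
}

# rbind data.frames whose column sets differ (missing columns become NA)
rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[, names(a), drop = FALSE])
}

# Truncated normal draws by inverse-CDF; truncation at mu +/- 4 sd intersected
# with [lower, upper] keeps all generated quantities inside physical bounds.
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  lo <- max(lower, mean - 4 * sd)
  hi <- min(upper, mean + 4 * sd)
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}
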