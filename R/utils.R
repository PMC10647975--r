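#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Parameter bounds for IVIM fitting
#'
#' Physiologic box constraints applied by both fitters, in SI units (mm^2/s
#' for diffusivities, fraction for the perfusion fraction). The pseudo-
#' diffusion coefficient is additionally constrained to exceed the slow
#' coefficient through the fit parameterisation.
#'
#' @return Named list with elements `d_slow`, `d_fast`, `f_p`, each a
#'   length-2 numeric `c(lower, upper)`.
#' @export
ivim_bounds <- function() {
  list(d_slow = c(0.1e-3, 3e-3),
       d_fast = c(3e-3, 300e-3),
       f_p    = c(0, 0.6))
}

#' Unit conversion between stored SI values and reported units
#'
#' Diffusivities are stored in mm^2/s and reported in 1e-3 mm^2/s; fractions
#' are stored in [0,1] and reported in percent. The two functions are exact
#' inverses of each other.
#'
#' @param x Numeric vector or array.
#' @param what One of `"diffusivity"` or `"fraction"`.
#' @return `x` rescaled to the other convention.
#' @export
si_to_report <- function(x, what = c("diffusivity", "fraction")) {
  what <- match.arg(what)
  if (what == "diffusivity") x * 1e3 else x * 100
}

#' @rdname si_to_report
#' @export
report_to_si <- function(x, what = c("diffusivity", "fraction")) {
  what <- match.arg(what)
  if (what == "diffusivity") x / 1e3 else x / 100
}

# deterministic per-subject / per-replicate seed derivation, kept within
# 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 101) %% 2147483629L)
}

# trapezoid quadrature weights for nodes t[1..k] (possibly non-uniform)
trapezoid_weights <- function(t) {
  k <- length(t)
  if (k == 1L) return(0)
  dt <- diff(t)
  w <- numeric(k)
  w[1] <- dt[1] / 2
  w[k] <- dt[k - 1] / 2
  if (k > 2L) w[2:(k - 1)] <- (dt[-(k - 1)] + dt[-1]) / 2
  w
}

# md5 of an R object via canonical JSON; used for config hashes and report
# digests so reruns can be compared bit-for-bit
object_md5 <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, na = "string",
                           force = TRUE)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(json, f)
  unname(tools::md5sum(f))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
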