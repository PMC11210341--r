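#' Thermal energy at room temperature
#'
#' Boltzmann thermal energy kB*T in piconewton-nanometres at T = 298 K.
#' All force-spectroscopy formulas in this package take `kbt` as an argument
#' defaulting to this constant, so a different temperature can be supplied.
#'
#' @format A length-one numeric, 4.114 pN nm.
#' @export
KBT_ROOM <- 4.114

# classed error helper: all package signals carry a "forcespec_error" class
# plus a specific subclass tests and callers can catch.
fs_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "forcespec_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fs_check <- function(ok, msg, class = "forcespec_invalid_argument") {
  if (!isTRUE(ok)) fs_abort(msg, class, call = sys.call(-2))
}

# positive scalar check used across the API
check_pos <- function(x, name) {
  fs_check(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
           sprintf("`%s` must be a single positive finite number", name))
}

#' Bell parameters (single-barrier dissociation model)
#'
#' Container for the Bell-Evans single-energy-barrier model of forced bond
#' dissociation: the zero-force off-rate `koff` (1/s) and the barrier width
#' `xbeta` (nm), the distance from the bound state to the transition state
#' along the pulling direction. Optional log-scale standard errors (base-10,
#' matching the convention of reporting errors in the exponent) may be
#' attached by fitting routines.
#'
#' @param koff zero-force off-rate, 1/s (> 0).
#' @param xbeta barrier width, nm (> 0).
#' @param se_log10_koff,se_log10_xbeta optional standard errors on
#'   log10(koff) and log10(xbeta).
#' @return An object of class `bell_parameters`.
#' @examples
#' bell_parameters(koff = 0.23, xbeta = 1.23)
#' @export
bell_parameters <- function(koff, xbeta, se_log10_koff = NA_real_,
                            se_log10_xbeta = NA_real_) {
  check_pos(koff, "koff")
  check_pos(xbeta, "xbeta")
  structure(
    list(koff = koff, xbeta = xbeta,
         se_log10_koff = se_log10_koff, se_log10_xbeta = se_log10_xbeta),
    class = "bell_parameters"
  )
}

#' @export
print.bell_parameters <- function(x, ...) {
  cat(sprintf("Bell-Evans parameters: koff = %.4g 1/s, xbeta = %.4g nm (%.4g Angstrom)\n",
              x$koff, x$xbeta, 10 * x$xbeta))
  if (is.finite(x$se_log10_koff))
    cat(sprintf("  log10 standard errors: koff %.3g, xbeta %.3g\n",
                x$se_log10_koff, x$se_log10_xbeta))
  invisible(x)
}
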