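#' Bell-Evans rupture-force distribution under a linear force ramp
#'
#' For a single bond obeying Bell kinetics, koff(F) = koff * exp(F*xbeta/kbt),
#' loaded at a constant rate r (pN/s), the rupture-force density is
#'
#'   p(F) = (koff/r) * exp(F*xbeta/kbt) *
#'          exp( (koff*kbt)/(r*xbeta) * (1 - exp(F*xbeta/kbt)) )
#'
#' with survival S(F) = exp( (koff*kbt)/(r*xbeta) * (1 - exp(F*xbeta/kbt)) ).
#' The most probable rupture force (the mode, when positive) is
#' F* = (kbt/xbeta) * log( r*xbeta / (koff*kbt) ).
#'
#' @param force force grid, pN (>= 0).
#' @param bell a [bell_parameters()] object.
#' @param loading_rate loading rate r, pN/s (> 0).
#' @param kbt thermal energy, pN nm.
#' @return `bell_density`/`bell_survival`: numeric vector along `force`;
#'   `bell_mode`: the most probable force F*, pN (0 if the analytic mode is
#'   negative, i.e. the distribution is monotone decreasing).
#' @seealso [sample_rupture_forces()], [fit_bell_ml()]
#' @export
bell_density <- function(force, bell, loading_rate, kbt = KBT_ROOM) {
  check_pos(loading_rate, "loading_rate")
  a <- bell$xbeta / kbt
  phi <- bell$koff * kbt / (loading_rate * bell$xbeta)
  d <- (bell$koff / loading_rate) * exp(a * force + phi * (1 - exp(a * force)))
  d[force < 0] <- 0
  d
}

#' @rdname bell_density
#' @export
bell_survival <- function(force, bell, loading_rate, kbt = KBT_ROOM) {
  check_pos(loading_rate, "loading_rate")
  a <- bell$xbeta / kbt
  phi <- bell$koff * kbt / (loading_rate * bell$xbeta)
  s <- exp(phi * (1 - exp(a * force)))
  s[force < 0] <- 1
  s
}

#' @rdname bell_density
#' @export
bell_mode <- function(bell, loading_rate, kbt = KBT_ROOM) {
  check_pos(loading_rate, "loading_rate")
  max(0, (kbt / bell$xbeta) * log(loading_rate * bell$xbeta / (bell$koff * kbt)))
}

# exact inverse-CDF transform: u in (0,1) -> rupture force.
# F = (kbt/xbeta) * log(1 - log(1-u)/phi); log(1-u) < 0 so the argument > 1.
bell_quantile <- function(u, bell, loading_rate, kbt = KBT_ROOM) {
  a <- bell$xbeta / kbt
  phi <- bell$koff * kbt / (loading_rate * bell$xbeta)
  log1p(-log1p(-u) / phi) / a
}

#' Sample single-bond rupture forces under Bell kinetics
#'
#' Draws i.i.d. rupture forces from the Bell-Evans distribution (see
#' [bell_density()]) by the exact inverse-CDF transform, so the sampler has
#' no discretisation error and is bit-reproducible under a seed.
#'
#' @inheritParams bell_density
#' @param n number of draws (>= 1).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return Numeric vector of `n` rupture forces, pN.
#' @examples
#' b <- bell_parameters(koff = 0.23, xbeta = 1.23)
#' f <- sample_rupture_forces(b, loading_rate = 1000, n = 1000, seed = 1)
#' mean(f)
#' @export
sample_rupture_forces <- function(bell, loading_rate, n, seed = NULL,
                                  kbt = KBT_ROOM) {
  check_pos(loading_rate, "loading_rate")
  fs_check(is.numeric(n) && length(n) == 1L && n >= 1 && n == round(n),
           "`n` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  bell_quantile(stats::runif(n), bell, loading_rate, kbt)
}

#' Sample double-bond rupture forces (uncorrelated two-bond Markov chain)
#'
#' Two identical, mechanically uncoupled bonds under a linear ramp F(t) = r*t.
#' The chain leaves state 2 (both bonds intact) at rate
#' 2*koff*exp(s*F*xbeta/kbt), where s is the per-bond load share (1/2 when the
#' bonds share the load, 1 when each bears the full load), and leaves state 1
#' at the single-bond rate koff*exp(F*xbeta/kbt). The returned force is the
#' ramp force at the final (state 1 -> 0) rupture.
#'
#' Both transition times are sampled exactly by inverting the analytic
#' cumulative hazards (no time stepping), so the only error is Monte-Carlo.
#'
#' @inheritParams sample_rupture_forces
#' @param load_sharing `"shared"` (s = 1/2, default) or `"full"` (s = 1).
#' @return Numeric vector of `n` final rupture forces, pN.
#' @seealso [predict_double_bond()] for the matching master-equation density,
#'   [sample_two_bond_lifetimes()] for the zero-load limit.
#' @export
sample_double_bond_forces <- function(bell, loading_rate, n, seed = NULL,
                                      load_sharing = c("shared", "full"),
                                      kbt = KBT_ROOM) {
  check_pos(loading_rate, "loading_rate")
  fs_check(is.numeric(n) && length(n) == 1L && n >= 1 && n == round(n),
           "`n` must be a positive integer")
  load_sharing <- match.arg(load_sharing)
  s <- if (load_sharing == "shared") 0.5 else 1
  if (!is.null(seed)) set.seed(seed)
  a <- bell$xbeta / kbt
  r <- loading_rate
  k <- bell$koff
  # state 2 -> 1: H2(F) = (2k)/(r*s*a) * (exp(s*a*F) - 1) = E1
  e1 <- stats::rexp(n)
  f1 <- log1p(e1 * r * s * a / (2 * k)) / (s * a)
  # state 1 -> 0 from F1: H1(F) = (k/(r*a)) * (exp(a*F) - exp(a*F1)) = E2
  e2 <- stats::rexp(n)
  log(exp(a * f1) + e2 * r * a / k) / a
}

#' Zero-load lifetimes of the uncorrelated two-bond system
#'
#' At zero force the two-bond Markov chain reduces to the sum of two
#' exponential holding times, Exp(2*koff) + Exp(koff), with mean 1.5/koff.
#' This is the basis of the whole-molecule off-rate reduction
#' koff_2bonds = koff/1.5 (see [two_bond_off_rate()]).
#'
#' @param koff single-bond off-rate, 1/s.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of `n` total lifetimes, s.
#' @export
sample_two_bond_lifetimes <- function(koff, n, seed = NULL) {
  check_pos(koff, "koff")
  fs_check(is.numeric(n) && length(n) == 1L && n >= 1, "`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(n, rate = 2 * koff) + stats::rexp(n, rate = koff)
}
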