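#' Worm-like chain force-extension law (Marko-Siggia interpolation)
#'
#' F(x) = (kbt/Lp) * ( 1/(4*(1 - x/Lc)^2) - 1/4 + x/Lc ), the standard
#' interpolated worm-like-chain (WLC) expression used to describe the
#' entropic elasticity of the PEG cross-linker and cell-membrane tether
#' stretched between tip and cell before a rupture.
#'
#' @param x extension, nm (0 <= x < Lc).
#' @param lc contour length, nm.
#' @param lp persistence length, nm.
#' @param kbt thermal energy, pN nm.
#' @return `wlc_force`: force, pN. `wlc_stiffness`: the analytic derivative
#'   dF/dx, pN/nm. `wlc_extension`: the inverse map, extension at force `f`.
#' @export
wlc_force <- function(x, lc, lp, kbt = KBT_ROOM) {
  xi <- x / lc
  (kbt / lp) * (1 / (4 * (1 - xi)^2) - 0.25 + xi)
}

#' @rdname wlc_force
#' @export
wlc_stiffness <- function(x, lc, lp, kbt = KBT_ROOM) {
  xi <- x / lc
  (kbt / lp) * (1 / (2 * (1 - xi)^3) + 1) / lc
}

#' @rdname wlc_force
#' @param f force, pN (>= 0).
#' @export
wlc_extension <- function(f, lc, lp, kbt = KBT_ROOM) {
  vapply(f, function(fi) {
    if (fi <= 0) return(0)
    stats::uniroot(function(x) wlc_force(x, lc, lp, kbt) - fi,
                   lower = 0, upper = lc * (1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Effective spring constant of cantilever and molecular linker in series
#'
#' The cantilever (stiffness `kc`) pulls the bond through the stretched
#' linker/membrane (stiffness `kl` at the point of rupture); the compliances
#' add, keff = (1/kc + 1/kl)^-1. keff is symmetric in its arguments and
#' bounded above by each.
#'
#' @param kc cantilever spring constant, pN/nm.
#' @param kl molecular (linker + membrane) stiffness at rupture, pN/nm.
#' @return Effective spring constant, pN/nm.
#' @examples
#' effective_spring_constant(10, 10)   # 5
#' effective_spring_constant(10, 0.35) # ~0.338: soft linker dominates
#' @export
effective_spring_constant <- function(kc, kl) {
  check_pos(kc, "kc")
  check_pos(kl, "kl")
  1 / (1 / kc + 1 / kl)
}

#' Loading rate at rupture
#'
#' r = retraction velocity x effective spring constant: the rate at which
#' force builds on the bond just before rupture.
#'
#' @param velocity retraction velocity, nm/s.
#' @param keff effective spring constant, pN/nm.
#' @return Loading rate, pN/s.
#' @export
loading_rate <- function(velocity, keff) {
  check_pos(velocity, "velocity")
  check_pos(keff, "keff")
  velocity * keff
}

#' Fit the pre-rupture stretch with a worm-like chain
#'
#' Least-squares fit of [wlc_force()] to the tensile stretch preceding a
#' rupture event, on tip-sample separation (piezo position corrected for
#' cantilever deflection, x = z - F/kc). The molecular stiffness at rupture,
#' `kl`, is the analytic derivative of the fitted WLC evaluated at the
#' rupture extension.
#'
#' On membrane-dominated (nearly linear) stretches the individual (Lc, Lp)
#' are weakly identified, but their combination fixing the local stiffness --
#' the quantity propagated to the loading rate -- is well determined.
#'
#' @param curve a [force_curve()].
#' @param event a rupture event for this curve (see [detect_events()]).
#' @param min_samples minimum number of stretch samples required.
#' @param min_force pN; samples below this tensile force are excluded
#'   (baseline / contact region).
#' @return A list with `lc`, `lp` (nm), `kl` (pN/nm, stiffness at the rupture
#'   force), `keff`, `loading_rate`, and `fit_status` ("wlc" or "linear" for
#'   the fallback local-slope estimate).
#' @export
fit_wlc <- function(curve, event, min_samples = 10, min_force = 2) {
  fs_check(inherits(curve, "force_curve"), "`curve` must be a force_curve")
  ret <- curve$segment == "retract"
  z <- curve$z[ret]; f <- curve$force[ret]
  upto <- z <= event$position & f > min_force
  # keep the contiguous stretch ending at the event
  idx <- which(upto)
  if (length(idx) >= 2) {
    brk <- which(diff(idx) > 3)
    if (length(brk) > 0) idx <- idx[(max(brk) + 1):length(idx)]
  }
  z <- z[idx]; f <- f[idx]
  x <- z - f / curve$kc  # tip-sample separation
  if (length(x) < max(min_samples, 3))
    fs_abort("too few stretch samples preceding the event for a WLC fit",
             class = "forcespec_fit_failure")
  fit <- tryCatch({
    x_end <- max(x)
    st <- list(lc = x_end * 1.5, lp = 0.4)
    minpack.lm::nlsLM(
      f ~ wlc_force(x, lc, lp),
      data = data.frame(x = x, f = f), start = st,
      lower = c(lc = x_end * 1.0000001, lp = 1e-4),
      upper = c(lc = x_end * 1e4, lp = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    x_rup <- wlc_extension(event$force, p$lc, p$lp)
    kl <- wlc_stiffness(x_rup, p$lc, p$lp)
    status <- "wlc"
    out <- list(lc = p$lc, lp = p$lp, kl = kl, fit_status = status)
  } else {
    # fallback: local linear slope over the final samples before rupture
    n <- length(x)
    tail_i <- max(1, n - 19):n
    sl <- stats::coef(stats::lm(f[tail_i] ~ x[tail_i]))[2]
    if (!is.finite(sl) || sl <= 0)
      fs_abort("WLC fit failed and local slope is not positive",
               class = "forcespec_fit_failure")
    out <- list(lc = NA_real_, lp = NA_real_, kl = unname(sl),
                fit_status = "linear")
  }
  out$keff <- effective_spring_constant(curve$kc, out$kl)
  out$loading_rate <- loading_rate(curve$velocity, out$keff)
  out
}

#' Assign loading rates to detected events
#'
#' Runs [fit_wlc()] for every event of a curve and fills the `loading_rate`,
#' `kl`, `keff` and `fit_status` columns. Events whose WLC fit and linear
#' fallback both fail are dropped with a warning.
#'
#' @param curve a [force_curve()].
#' @param events data frame from [detect_events()].
#' @return `events` augmented with elasticity columns.
#' @export
annotate_loading_rates <- function(curve, events) {
  if (nrow(events) == 0) {
    events$kl <- events$keff <- events$loading_rate <- numeric(0)
    events$fit_status <- character(0)
    return(events)
  }
  res <- lapply(seq_len(nrow(events)), function(i) {
    tryCatch(fit_wlc(curve, events[i, ]),
             forcespec_fit_failure = function(e) NULL)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (any(!keep))
    warning(sprintf("curve %s: %d event(s) dropped (elasticity fit failed)",
                    curve$curve_id, sum(!keep)))
  events <- events[keep, , drop = FALSE]
  res <- res[keep]
  events$kl <- vapply(res, `[[`, numeric(1), "kl")
  events$keff <- vapply(res, `[[`, numeric(1), "keff")
  events$loading_rate <- vapply(res, `[[`, numeric(1), "loading_rate")
  events$fit_status <- vapply(res, `[[`, character(1), "fit_status")
  events
}
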