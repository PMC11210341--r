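#' Probability density function of unbinding forces
#'
#' Each measured rupture force contributes one Gaussian of unit area centred
#' at the force with width equal to its measurement error (the thermal
#' cantilever fluctuation after unbinding, typically a few pN); the Gaussians
#' are summed on a regular grid. The PDF is the continuous equivalent of a
#' force histogram: its maxima are the most probable unbinding forces, and
#' its trapezoidal integral equals the number of events.
#'
#' @param events data frame with columns `force` and `noise_sd`.
#' @param grid_step force grid spacing, pN.
#' @return An object of class `force_pdf`: list with `grid`, `density`
#'   (per pN), `n_events`.
#' @export
build_pdf <- function(events, grid_step = 0.2) {
  fs_check(is.data.frame(events) && nrow(events) >= 1,
           "`events` must contain at least one event")
  fs_check(all(c("force", "noise_sd") %in% names(events)),
           "`events` needs `force` and `noise_sd` columns")
  check_pos(grid_step, "grid_step")
  fmax <- max(events$force) + 5 * max(events$noise_sd)
  grid <- seq(0, fmax, by = grid_step)
  dens <- rowSums(vapply(seq_len(nrow(events)), function(i) {
    stats::dnorm(grid, events$force[i], events$noise_sd[i])
  }, numeric(length(grid))))
  structure(list(grid = grid, density = dens, n_events = nrow(events)),
            class = "force_pdf")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.force_pdf <- function(x, ...) {
  cat(sprintf("<force_pdf> %d events, grid 0..%.1f pN, mode at %.1f pN\n",
              x$n_events, max(x$grid), x$grid[which.max(x$density)]))
  invisible(x)
}

#' Bimodal (two-Gaussian) decomposition of unbinding forces
#'
#' Unbinding-force distributions of bivalent binders are bimodal: the lower
#' mode from single-bond ruptures, the upper from double bonds. The mixture
#' is fitted by maximum likelihood on the raw forces (two-component Gaussian
#' mixture with unequal variances); the summed-Gaussian PDF is a display and
#' cross-check surface, not the fit target. Components are ordered so
#' `mu1 < mu2`.
#'
#' @param forces numeric vector of rupture forces (pN), or a data frame with
#'   a `force` column.
#' @param min_events minimum number of events required (default 20).
#' @param min_weight smallest admissible component weight; below it the fit
#'   is declared degenerate.
#' @return An object of class `bimodal_fit`: `mu1`, `sigma1`, `w1`, `mu2`,
#'   `sigma2`, `w2`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_bimodal <- function(forces, min_events = 20, min_weight = 0.02) {
  if (is.data.frame(forces)) forces <- forces$force
  fs_check(is.numeric(forces) && length(forces) >= min_events,
           sprintf("need at least %d events for a bimodal fit", min_events))
  fit <- tryCatch(
    mclust::Mclust(forces, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    fs_abort("two-component mixture fit did not converge",
             class = "forcespec_degenerate_fit")
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- unname(mu[o]); sig <- unname(sig[o]); w <- unname(w[o])
  if (min(w) < min_weight)
    fs_abort(sprintf("mixture degenerate: component weight %.3g < %.3g",
                     min(w), min_weight),
             class = "forcespec_degenerate_fit")
  structure(list(mu1 = mu[1], sigma1 = sig[1], w1 = w[1],
                 mu2 = mu[2], sigma2 = sig[2], w2 = w[2]),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf("<bimodal_fit> %.0f%% N(%.1f, %.1f^2) + %.0f%% N(%.1f, %.1f^2) pN\n",
              100 * x$w1, x$mu1, x$sigma1, 100 * x$w2, x$mu2, x$sigma2))
  invisible(x)
}

#' Gate single-bond events
#'
#' Keeps events whose force lies within mu1 +/- 2*sigma1 of the first (lower)
#' Gaussian of the bimodal decomposition -- the single-bond population window
#' used before Bell-Evans fitting.
#'
#' @param events data frame with a `force` column.
#' @param bimodal a [fit_bimodal()] result.
#' @param n_sigma half-width of the gate in sigma units (default 2).
#' @return The gated subset of `events`.
#' @export
gate_single_bond <- function(events, bimodal, n_sigma = 2) {
  fs_check(inherits(bimodal, "bimodal_fit"), "`bimodal` must be a bimodal_fit")
  lo <- bimodal$mu1 - n_sigma * bimodal$sigma1
  hi <- bimodal$mu1 + n_sigma * bimodal$sigma1
  events[events$force >= lo & events$force <= hi, , drop = FALSE]
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal Jacobi
# matrix); used for the optional measurement-error convolution.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Maximum-likelihood Bell-Evans fit of gated single-bond events
#'
#' Maximises the log-likelihood of the observed (force, loading-rate) pairs
#' under the Bell-Evans rupture-force density (see [bell_density()]) in the
#' parameters (log koff, log xbeta). Standard errors on log10(koff) and
#' log10(xbeta) come from the observed information (inverse Hessian at the
#' optimum). Optionally each event's density is convolved with its Gaussian
#' measurement error `noise_sd` (Gauss-Hermite quadrature); the default fits
#' the raw forces, and both modes are exercised in the test-suite.
#'
#' @param events data frame with columns `force`, `loading_rate`, and (for
#'   `convolve_error = TRUE`) `noise_sd`.
#' @param convolve_error include per-event Gaussian measurement error in the
#'   likelihood.
#' @param window optional force window `c(lo, hi)` (pN) to which the events
#'   were gated (e.g. the +/- 2 sigma single-bond gate): the density is
#'   renormalised over the window, so the fit is unbiased under the
#'   truncation that gating introduces.
#' @param kbt thermal energy, pN nm.
#' @param min_events,min_rate_span below these a warning is issued (the fit
#'   still runs): too few events, or loading rates spanning less than the
#'   given factor, give poorly constrained estimates.
#' @param gh_nodes quadrature nodes for the error convolution.
#' @return A [bell_parameters()] object with log10-scale standard errors and
#'   attributes `logLik`, `n_events`, and `fstar` (function of r returning
#'   the fitted most-probable-force line for display against binned data).
#' @export
fit_bell_ml <- function(events, convolve_error = FALSE, window = NULL,
                        kbt = KBT_ROOM,
                        min_events = 50, min_rate_span = 5, gh_nodes = 21) {
  fs_check(is.data.frame(events) && nrow(events) >= 2,
           "`events` must contain at least 2 rows")
  fs_check(all(c("force", "loading_rate") %in% names(events)),
           "`events` needs `force` and `loading_rate` columns")
  f <- events$force
  r <- events$loading_rate
  fs_check(all(is.finite(f)) && all(is.finite(r)) && all(r > 0),
           "forces and loading rates must be finite and rates positive")
  if (nrow(events) < min_events)
    warning(sprintf("only %d events; Bell-Evans estimates may be unstable",
                    nrow(events)))
  if (max(r) / min(r) < min_rate_span)
    warning(sprintf("loading rates span < factor %g; xbeta weakly constrained",
                    min_rate_span))
  sig <- if (convolve_error) events$noise_sd else NULL
  gh <- if (convolve_error) gauss_hermite(gh_nodes) else NULL

  if (!is.null(window))
    fs_check(length(window) == 2 && window[1] < window[2],
             "`window` must be c(lo, hi) with lo < hi")

  dens1 <- function(ff, rr, koff, xbeta) {
    a <- xbeta / kbt
    phi <- koff * kbt / (rr * xbeta)
    out <- (koff / rr) * exp(a * ff + phi * (1 - exp(a * ff)))
    out[ff < 0] <- 0
    out
  }
  surv1 <- function(ff, rr, koff, xbeta) {
    a <- xbeta / kbt
    phi <- koff * kbt / (rr * xbeta)
    exp(phi * (1 - exp(a * pmax(ff, 0))))
  }
  nll <- function(theta) {
    koff <- exp(theta[1]); xbeta <- exp(theta[2])
    if (!is.finite(koff) || !is.finite(xbeta)) return(1e12)
    if (is.null(sig)) {
      d <- dens1(f, r, koff, xbeta)
    } else {
      d <- numeric(length(f))
      for (q in seq_along(gh$nodes)) {
        d <- d + gh$weights[q] / sqrt(pi) *
          dens1(f - sqrt(2) * sig * gh$nodes[q], r, koff, xbeta)
      }
    }
    if (!is.null(window)) {
      # probability mass of the gate window per event: P(lo <= F + sigma*U <= hi)
      # with F ~ Bell, U ~ N(0,1); the Gaussian expectation uses the same
      # Gauss-Hermite rule as the density
      if (is.null(sig)) {
        zmass <- surv1(window[1], r, koff, xbeta) -
          surv1(window[2], r, koff, xbeta)
      } else {
        zmass <- numeric(length(f))
        for (q in seq_along(gh$nodes)) {
          u <- sqrt(2) * gh$nodes[q]
          zmass <- zmass + gh$weights[q] / sqrt(pi) *
            (surv1(window[1] - sig * u, r, koff, xbeta) -
               surv1(window[2] - sig * u, r, koff, xbeta))
        }
      }
      d <- d / pmax(zmass, 1e-12)
    }
    v <- -sum(log(pmax(d, 1e-300)))
    if (!is.finite(v)) 1e12 else v
  }

  # initial values from the mean-force-vs-log-rate line when rates vary
  koff0 <- 0.1; xbeta0 <- 1
  if (length(unique(r)) >= 2) {
    agg <- stats::aggregate(f, list(r = r), mean)
    if (nrow(agg) >= 2) {
      co <- unname(stats::coef(stats::lm(agg$x ~ log(agg$r))))
      b <- co[2]
      if (is.finite(b) && b > 0) {
        xbeta0 <- kbt / b
        k0 <- xbeta0 / (kbt * exp(co[1] / b))
        if (is.finite(k0) && k0 > 0) koff0 <- k0
      }
    }
  }
  # simplex first (robust to the underflow plateau far from the optimum),
  # then a quasi-Newton polish that also yields the observed information
  opt0 <- stats::optim(c(log(koff0), log(xbeta0)), nll,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt0$par, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  if (opt$value > opt0$value + 1e-6) {  # polish went astray: keep simplex
    opt <- opt0
    opt$hessian <- stats::optimHess(opt0$par, nll)
  }
  if (opt$convergence != 0)
    fs_abort(sprintf("Bell-Evans ML fit did not converge (code %d)",
                     opt$convergence),
             class = "forcespec_fit_failure")
  se_ln <- c(NA_real_, NA_real_)
  ev <- eigen(opt$hessian, symmetric = TRUE, only.values = TRUE)$values
  vc <- if (all(ev > 0)) tryCatch(solve(opt$hessian), error = function(e) NULL)
        else NULL
  if (!is.null(vc) && all(diag(vc) > 0)) {
    se_ln <- sqrt(diag(vc))
  } else {
    warning("observed information not positive definite; errors undefined")
  }
  koff <- exp(opt$par[1]); xbeta <- exp(opt$par[2])
  out <- bell_parameters(koff, xbeta,
                         se_log10_koff = se_ln[1] / log(10),
                         se_log10_xbeta = se_ln[2] / log(10))
  attr(out, "logLik") <- -opt$value
  attr(out, "n_events") <- nrow(events)
  attr(out, "se_ln") <- se_ln
  attr(out, "fstar") <- function(rr) {
    pmax(0, (kbt / xbeta) * log(rr * xbeta / (koff * kbt)))
  }
  out
}

#' Whole-molecule (two-bond) off-rate from the single-bond off-rate
#'
#' For two identical, uncorrelated bonds the mean zero-load lifetime is
#' 1/(2*koff) + 1/koff = 1.5/koff, so the overall dissociation rate of the
#' bivalent molecule is koff_2bonds = koff/1.5.
#'
#' @param koff single-bond off-rate, 1/s.
#' @return koff/1.5, 1/s.
#' @examples
#' two_bond_off_rate(0.23) # 0.1533... (reported as 0.15)
#' @export
two_bond_off_rate <- function(koff) {
  check_pos(koff, "koff")
  koff / 1.5
}

#' Bond lifetime
#'
#' tau = 1/koff, the mean lifetime of the bond at zero force.
#'
#' @param koff off-rate, 1/s.
#' @return Lifetime, s.
#' @examples
#' bond_lifetime(0.23) # 4.35 s
#' @export
bond_lifetime <- function(koff) {
  check_pos(koff, "koff")
  1 / koff
}

#' Master-equation prediction of double-bond rupture forces
#'
#' Numerically integrates the two-state Markov dissociation under a linear
#' force ramp (the same model as [sample_double_bond_forces()], solved as a
#' master equation rather than by Monte Carlo): occupancy of state 2 decays
#' at rate 2*koff*exp(s*F*xbeta/kbt), feeds state 1, which decays at the
#' single-bond rate; the final-rupture force density is
#' rho(F) = k1(F) * P1(F) / r. State-2 occupancy is analytic; state 1 is
#' integrated with `deSolve::lsoda` on a force grid (relative tolerance
#' 1e-10), and the density is renormalised for the (numerically negligible)
#' truncation of the grid.
#'
#' @param bell a [bell_parameters()] object (single-bond parameters).
#' @param loading_rates loading rates, pN/s.
#' @param load_sharing `"shared"` (s = 1/2) or `"full"` (s = 1).
#' @param kbt thermal energy, pN nm.
#' @param n_grid force-grid resolution per rate.
#' @return A list with one element per loading rate, each containing `grid`,
#'   `density`, `cdf`, and `mode` (pN); plus a `modes` vector attribute.
#' @export
predict_double_bond <- function(bell, loading_rates,
                                load_sharing = c("shared", "full"),
                                kbt = KBT_ROOM, n_grid = 2000) {
  fs_check(inherits(bell, "bell_parameters"), "`bell` must be bell_parameters")
  fs_check(all(loading_rates > 0), "loading rates must be positive")
  load_sharing <- match.arg(load_sharing)
  s <- if (load_sharing == "shared") 0.5 else 1
  a <- bell$xbeta / kbt
  k <- bell$koff
  res <- lapply(loading_rates, function(r) {
    # grid wide enough that even the last of two full-load bonds has ruptured
    fmax <- 1.5 * bell_quantile(1 - 1e-12, bell, r, kbt) + 10
    grid <- seq(0, fmax, length.out = n_grid)
    p2 <- function(F) exp(-(2 * k) / (r * s * a) * (exp(s * a * F) - 1))
    rhs <- function(F, y, parms) {
      h2 <- 2 * k * exp(s * a * F)
      h1 <- k * exp(a * F)
      list((h2 * p2(F) - h1 * y[1]) / r)
    }
    sol <- deSolve::lsoda(c(p1 = 0), grid, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    p1 <- pmax(0, sol[, "p1"])
    dens <- k * exp(a * grid) * p1 / r
    z <- trapz(grid, dens)
    if (!is.finite(z) || z <= 0)
      fs_abort("master-equation integration failed",
               class = "forcespec_numeric_failure")
    dens <- dens / z
    cdf <- cumsum(c(0, diff(grid) * (utils::head(dens, -1) +
                                       utils::tail(dens, -1)) / 2))
    cdf <- cdf / max(cdf)
    i <- which.max(dens)
    # quadratic refinement of the grid mode
    mode <- grid[i]
    if (i > 1 && i < length(grid)) {
      y <- dens[(i - 1):(i + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (denom < 0) mode <- grid[i] + 0.5 * (y[1] - y[3]) / denom * diff(grid)[1]
    }
    list(grid = grid, density = dens, cdf = cdf, mode = mode)
  })
  names(res) <- as.character(loading_rates)
  attr(res, "modes") <- vapply(res, `[[`, numeric(1), "mode")
  res
}
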