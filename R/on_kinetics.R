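#' Effective concentration of the tip-tethered ligand
#'
#' A single ligand tethered to the AFM tip by a flexible cross-linker
#' explores a hemisphere of radius r_eff = linker length + half ligand
#' length; its effective molar concentration is Ceff = 1/(N_A * V) with
#' V = (2/3)*pi*r_eff^3. With the canonical ~6 nm PEG linker and ~4 nm
#' antibody half-length, Ceff is about 7.9e-4 M.
#'
#' @param linker_length cross-linker equilibrium length, nm.
#' @param antibody_half_length half-length of the tethered ligand, nm.
#' @return Effective concentration, mol/L.
#' @examples
#' effective_concentration(6, 4) # ~7.93e-4 M
#' @export
effective_concentration <- function(linker_length = 6, antibody_half_length = 4) {
  check_pos(linker_length, "linker_length")
  check_pos(antibody_half_length, "antibody_half_length")
  r_eff <- linker_length + antibody_half_length     # nm
  v_l <- (2 / 3) * pi * r_eff^3 * 1e-24             # nm^3 -> L
  1 / (6.02214076e23 * v_l)
}

#' Fit binding probability versus dwell time (pseudo-first-order model)
#'
#' Weighted least-squares fit of P(t) = A * (1 - exp(-(t - t0)/tau)), clipped
#' at 0 for t < t0: `A` is the saturated binding probability, `t0` the lag
#' time (constrained >= 0) and `tau` the characteristic association time.
#' Weights default to inverse binomial variance when per-point curve counts
#' are given (with a +0.5/n variance stabiliser at 0% / 100% points);
#' unweighted fitting is available for parity with a plain least-squares
#' reading.
#'
#' @param dwell_times dwell times, s (>= 4 points).
#' @param probabilities binding probabilities in \[0, 1\].
#' @param n_curves optional per-point number of curves (for binomial
#'   weights).
#' @param weights optional explicit weights (overrides `n_curves`).
#' @return List with `A`, `t0`, `tau`, their standard errors (`se_A`,
#'   `se_t0`, `se_tau`), and the `fit` object.
#' @export
fit_dwell_curve <- function(dwell_times, probabilities, n_curves = NULL,
                            weights = NULL) {
  fs_check(length(dwell_times) == length(probabilities) &&
             length(dwell_times) >= 4,
           "need >= 4 (dwell, probability) pairs")
  fs_check(all(probabilities >= 0 & probabilities <= 1),
           "probabilities must lie in [0, 1]")
  if (all(probabilities == 0))
    fs_abort("all probabilities are zero: no association signal",
             class = "forcespec_fit_failure")
  if (is.null(weights)) {
    if (!is.null(n_curves)) {
      v <- (probabilities * (1 - probabilities) + 0.5 / n_curves) / n_curves
      weights <- 1 / v
    } else {
      weights <- rep(1, length(dwell_times))
    }
  }
  df <- data.frame(t = dwell_times, p = probabilities, w = weights)
  fit <- NULL
  err <- NULL
  for (tau0 in c(stats::median(dwell_times), max(dwell_times) / 5,
                 2 * min(dwell_times[dwell_times > 0]))) {
    start <- list(A = min(1, max(probabilities)), t0 = 0, tau = tau0)
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ A * (1 - exp(-(pmax(t - t0, 0)) / tau)),
                        data = df, start = start, weights = w,
                        lower = c(A = 1e-6, t0 = 0, tau = 1e-8),
                        upper = c(A = 1, t0 = max(dwell_times), tau = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    fs_abort(paste0("dwell-curve fit failed: ", conditionMessage(err)),
             class = "forcespec_fit_failure")
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (co["A"] >= 1 - 1e-9)
    warning("saturated binding probability A pinned to its upper bound")
  list(A = unname(co["A"]), t0 = unname(co["t0"]), tau = unname(co["tau"]),
       se_A = unname(se["A"]), se_t0 = unname(se["t0"]),
       se_tau = unname(se["tau"]), fit = fit)
}

#' Association rate from the characteristic dwell time
#'
#' Pseudo-first-order inversion kon = 1/(tau * Ceff): the dwell-time constant
#' tau of the saturating binding-probability curve together with the
#' effective concentration of the single tethered ligand gives the bimolecular
#' association rate.
#'
#' @param tau characteristic association time, s.
#' @param ceff effective concentration, mol/L.
#' @return kon, 1/(M s).
#' @examples
#' on_rate(0.0263, effective_concentration(6, 4)) # ~4.8e4 1/(M s)
#' @export
on_rate <- function(tau, ceff) {
  check_pos(tau, "tau")
  check_pos(ceff, "ceff")
  1 / (tau * ceff)
}

#' Second-bond formation rate from double-bond fractions
#'
#' Fits the same saturating-exponential form as [fit_dwell_curve()] to the
#' fraction of curves showing double-bond ruptures and reports
#' kon2 = 1/tau2 in 1/s -- a unimolecular rate, since the second bond forms
#' while the first already holds the ligand at the surface (no concentration
#' conversion).
#'
#' @inheritParams fit_dwell_curve
#' @param double_fractions per-dwell fraction of double-bond curves.
#' @return List with `kon2` (1/s), `se_log10_kon2`, and the underlying
#'   dwell-curve fit.
#' @export
two_bond_on_rate <- function(dwell_times, double_fractions, n_curves = NULL,
                             weights = NULL) {
  if (all(double_fractions == 0))
    fs_abort("all double-bond fractions are zero: no second-bond signal",
             class = "forcespec_fit_failure")
  fit <- fit_dwell_curve(dwell_times, double_fractions, n_curves = n_curves,
                         weights = weights)
  kon2 <- 1 / fit$tau
  se_log10 <- if (is.finite(fit$se_tau)) fit$se_tau / fit$tau / log(10) else NA_real_
  list(kon2 = kon2, se_log10_kon2 = se_log10, dwell_fit = fit)
}

#' Association analysis of a simulated or measured experiment
#'
#' Computes per-dwell binding probabilities and double-bond fractions across
#' the cells of a `curve_experiment` (or a list of [curve_set()]s), fits the
#' pseudo-first-order association model for both, and converts to kon (via
#' the effective concentration) and kon2.
#'
#' @param experiment a `curve_experiment` from [simulate_experiment()] or a
#'   list of [curve_set()]s with distinct dwell times.
#' @param linker_length,antibody_half_length geometry for
#'   [effective_concentration()].
#' @param snr_threshold passed to [detect_events()].
#' @param events_by_cell optional precomputed detection results (list, per
#'   cell, of per-curve event tables) to avoid re-detection.
#' @param double_force_cutoff passed to [binding_probability()]: single-drop
#'   curves above this force count as simultaneous double ruptures.
#' @return An object of class `on_rate_fit`: `A`, `t0`, `tau`, `ceff`,
#'   `kon`, `kon2`, log10-scale errors, and the per-dwell `table`.
#' @export
association_analysis <- function(experiment, linker_length = 6,
                                 antibody_half_length = 4,
                                 snr_threshold = 2, events_by_cell = NULL,
                                 double_force_cutoff = NULL) {
  cells <- if (inherits(experiment, "curve_experiment")) experiment$cells
           else experiment
  fs_check(is.list(cells) && length(cells) >= 4,
           "need >= 4 dwell-time cells for association analysis")
  tab <- do.call(rbind, lapply(seq_along(cells), function(i) {
    cs <- cells[[i]]
    if (!is.null(events_by_cell)) {
      row <- binding_probability(events_by_cell[[i]],
                                 double_force_cutoff = double_force_cutoff)
    } else {
      row <- binding_probability(cs, snr_threshold = snr_threshold,
                                 double_force_cutoff = double_force_cutoff)
    }
    # dwell as the analysis would measure it: from the contact region of the
    # curves, not the nominal grid value (short nominal dwells floor at the
    # contact travel time)
    row$dwell_time_s <- stats::median(
      vapply(cs$curves, compute_dwell_time, numeric(1)))
    row$dwell_nominal_s <- cs$dwell_time_s
    row
  }))
  rownames(tab) <- NULL
  tab <- tab[order(tab$dwell_time_s), ]
  fit <- fit_dwell_curve(tab$dwell_time_s, tab$probability,
                         n_curves = tab$n_curves)
  ceff <- effective_concentration(linker_length, antibody_half_length)
  kon <- on_rate(fit$tau, ceff)
  se_log10_kon <- if (is.finite(fit$se_tau)) fit$se_tau / fit$tau / log(10)
                  else NA_real_
  k2 <- tryCatch(
    two_bond_on_rate(tab$dwell_time_s, tab$double_fraction,
                     n_curves = tab$n_curves),
    forcespec_fit_failure = function(e) list(kon2 = NA_real_,
                                             se_log10_kon2 = NA_real_))
  structure(
    list(A = fit$A, t0 = fit$t0, tau = fit$tau,
         se_A = fit$se_A, se_tau = fit$se_tau,
         ceff = ceff, kon = kon, se_log10_kon = se_log10_kon,
         kon2 = k2$kon2, se_log10_kon2 = k2$se_log10_kon2,
         table = tab),
    class = "on_rate_fit")
}

#' @export
print.on_rate_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<on_rate_fit> A = %.3g, t0 = %.3g s, tau = %.4g s\n",
    "  Ceff = %.3g M, kon = %.3g 1/(M s), kon2 = %.3g 1/s\n"),
    x$A, x$t0, x$tau, x$ceff, x$kon, x$kon2))
  invisible(x)
}
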