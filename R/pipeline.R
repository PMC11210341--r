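#' Full kinetic analysis of one experimental condition
#'
#' Runs the complete pipeline on a `curve_experiment` (typically from
#' [simulate_experiment()], or assembled from measured curve sets): event
#' detection and classification in every cell, worm-like-chain loading-rate
#' assignment of each curve's final rupture, bimodal decomposition of the
#' pooled unbinding forces, +/- 2 sigma single-bond gating, Bell-Evans
#' maximum-likelihood fit, dwell-time association analysis (with the
#' high-force population counted toward double-bond formation), and assembly
#' into a [summarize_kinetics()] report.
#'
#' Detection runs once per curve; all downstream stages reuse it.
#'
#' @param experiment a `curve_experiment`.
#' @param condition label for the report.
#' @param snr_threshold detection threshold, see [detect_events()].
#' @param linker_length,antibody_half_length geometry for
#'   [effective_concentration()].
#' @param convolve_error passed to [fit_bell_ml()]. Defaults to `TRUE` here:
#'   detected forces carry a few-pN measurement error, and fitting raw forces
#'   without deconvolution inflates the apparent off-rate several-fold.
#' @return A list: `summary` ([summarize_kinetics()]), `bell`, `on`,
#'   `bimodal` (`NULL` if the force distribution was effectively unimodal),
#'   `events` (annotated final-rupture table), `gated_events`, and the
#'   per-cell association `table`.
#' @export
analyze_experiment <- function(experiment, condition = "condition",
                               snr_threshold = 2, linker_length = 6,
                               antibody_half_length = 4,
                               convolve_error = TRUE) {
  fs_check(inherits(experiment, "curve_experiment"),
           "`experiment` must be a curve_experiment")
  events_by_cell <- lapply(experiment$cells, function(cs) {
    lapply(cs$curves, detect_events, snr_threshold = snr_threshold)
  })

  # final-rupture table with loading rates, for the force analysis
  finals <- do.call(rbind, unlist(lapply(names(experiment$cells), function(nm) {
    cs <- experiment$cells[[nm]]
    lapply(seq_along(cs$curves), function(i) {
      ev <- events_by_cell[[nm]][[i]]
      if (nrow(ev) == 0) return(NULL)
      ev <- ev[nrow(ev), , drop = FALSE]
      suppressWarnings(annotate_loading_rates(cs$curves[[i]], ev))
    })
  }), recursive = FALSE))
  fs_check(!is.null(finals) && nrow(finals) >= 20,
           "too few detected events for kinetic analysis")
  rownames(finals) <- NULL

  bim <- tryCatch(fit_bimodal(finals),
                  forcespec_degenerate_fit = function(e) NULL)
  gated <- if (is.null(bim)) finals else gate_single_bond(finals, bim)
  gate_window <- if (is.null(bim)) NULL
                 else c(bim$mu1 - 2 * bim$sigma1, bim$mu1 + 2 * bim$sigma1)
  bell <- suppressWarnings(fit_bell_ml(gated, convolve_error = convolve_error,
                                       window = gate_window))

  cutoff <- if (is.null(bim)) NULL else bim$mu1 + 2 * bim$sigma1
  on <- association_analysis(experiment, linker_length = linker_length,
                             antibody_half_length = antibody_half_length,
                             events_by_cell = events_by_cell,
                             double_force_cutoff = cutoff)
  list(summary = summarize_kinetics(bell, on, condition = condition),
       bell = bell, on = on, bimodal = bim,
       events = finals, gated_events = gated, table = on$table)
}

#' Bin events by loading rate for force-vs-rate display
#'
#' Log-spaced loading-rate bins, returning per-bin mean and sd of the
#' unbinding force -- the binned overlay conventionally drawn on top of the
#' fitted most-probable-force line. Bins with fewer than `min_per_bin`
#' events are dropped.
#'
#' @param events annotated event table with `force` and `loading_rate`.
#' @param n_bins target number of log-spaced bins.
#' @param min_per_bin minimum events per reported bin.
#' @return Data frame: `rate_mid`, `n`, `mean_force`, `sd_force`.
#' @export
bin_by_loading_rate <- function(events, n_bins = 8, min_per_bin = 15) {
  fs_check(nrow(events) >= min_per_bin, "too few events to bin")
  lr <- log(events$loading_rate)
  brk <- seq(min(lr), max(lr), length.out = n_bins + 1)
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  idx <- findInterval(lr, brk, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(rate_mid = exp(mean(brk[b:(b + 1)])), n = sum(sel),
               mean_force = mean(events$force[sel]),
               sd_force = stats::sd(events$force[sel]))
  }))
  out[out$n >= min_per_bin, , drop = FALSE]
}
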