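#' Detect rupture events in a retract trace
#'
#' Candidate ruptures are local maxima of tensile force in the (median-
#' smoothed) retract trace that are followed by a sharp, sustained drop back
#' toward baseline. An event is reported iff its force step is at least
#' `snr_threshold` times the local baseline noise sd, estimated robustly
#' (MAD) from a fixed-width window after the drop. Smoothing is used only to
#' locate candidates; reported forces come from the unsmoothed data.
#'
#' @param curve a [force_curve()] with a retract segment.
#' @param snr_threshold signal-to-noise acceptance threshold (default 2).
#' @param smooth_width running-median width for candidate search, samples.
#' @param baseline_window post-rupture window for the local noise estimate,
#'   samples.
#' @param drop_span samples within which the sharp drop must occur.
#' @return A data frame with one row per event, ordered by position:
#'   `order`, `force` (pN, unsmoothed), `position` (nm, piezo z at rupture),
#'   `noise_sd` (pN), `curve_id`.
#' @export
detect_events <- function(curve, snr_threshold = 2, smooth_width = 5,
                          baseline_window = 50, drop_span = 10) {
  fs_check(inherits(curve, "force_curve"), "`curve` must be a force_curve")
  check_pos(snr_threshold, "snr_threshold")
  ret <- which(curve$segment == "retract")
  fs_check(length(ret) >= smooth_width + baseline_window,
           "curve has no (or too short) retract segment")
  f <- curve$force[ret]
  z <- curve$z[ret]
  n <- length(f)
  sm <- stats::runmed(f, k = smooth_width, endrule = "median")

  # global baseline noise from the far (large-z) quarter of the retract
  far <- seq.int(floor(3 * n / 4), n)
  sd_global <- stats::mad(f[far])
  if (!is.finite(sd_global) || sd_global == 0) sd_global <- stats::sd(f[far])
  if (!is.finite(sd_global) || sd_global == 0) sd_global <- .Machine$double.eps

  # sharp downward steps of the smoothed trace locate candidate ruptures
  gap <- drop_span %/% 2
  step <- sm[seq_len(n - gap)] - sm[seq_len(n - gap) + gap]
  cand <- integer(0)
  for (i in seq.int(gap + 1L, n - baseline_window - drop_span)) {
    win <- step[max(1L, i - gap):min(length(step), i + gap)]
    if (step[i] > 0 && step[i] >= max(win) && sm[i] > 0) cand <- c(cand, i)
  }
  # candidates within one drop span form a cluster: keep the largest step,
  # breaking exact ties toward the later (larger-separation) sample
  if (length(cand) > 1) {
    cl <- cumsum(c(1L, diff(cand) > drop_span))
    cand <- vapply(split(cand, cl), function(ix) {
      s <- step[ix]
      ix[max(which(s == max(s)))]
    }, integer(1))
  }

  pre_window <- 8L
  rows <- list()
  for (i in cand) {
    # anchor the event at the steepest single-sample drop near the candidate:
    # exact on noiseless fixtures, unbiased under noise
    jj <- max(2L, i - gap):min(n - 1L, i + gap)
    p <- jj[which.max(f[jj] - f[jj + 1L])]
    post <- (p + drop_span):min(n, p + drop_span + baseline_window - 1L)
    base_post <- stats::median(f[post])
    noise <- stats::mad(f[post])
    if (!is.finite(noise) || noise == 0) noise <- sd_global
    thr <- snr_threshold * max(noise, sd_global)
    # force step estimated between short window means flanking the drop,
    # so its own noise is well below the per-sample sd
    pre <- mean(f[max(1L, p - pre_window + 1L):p])
    sharp <- sm[p] - min(sm[p:min(n, p + drop_span)])  # fast component
    if (pre - base_post >= thr && sharp >= thr &&
        sm[p] >= snr_threshold * sd_global) {
      # force reported from the unsmoothed trace at the rupture sample
      rows[[length(rows) + 1L]] <-
        data.frame(force = f[p] - base_post, position = z[p],
                   noise_sd = noise, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(order = integer(0), force = numeric(0),
                      position = numeric(0), noise_sd = numeric(0),
                      curve_id = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  out$order <- seq_len(nrow(out))
  out$curve_id <- curve$curve_id
  rownames(out) <- NULL
  out[, c("order", "force", "position", "noise_sd", "curve_id")]
}

#' Classify a curve by bond multiplicity
#'
#' 0 events: `"none"`; 1: `"single"`; 2 separated by at most
#' `simultaneity_window`: `"double_simultaneous"`; 2 farther apart:
#' `"double_sequential"`. Curves with more than two events are classified by
#' their last two (a warning is logged); such curves are rare and the rule is
#' a documented package choice.
#'
#' @param events data frame from [detect_events()] for one curve.
#' @param simultaneity_window nm; default 5.
#' @return A string, one of the four binding classes.
#' @export
classify_curve <- function(events, simultaneity_window = 5) {
  n <- nrow(events)
  if (n == 0) return("none")
  if (n == 1) return("single")
  if (n > 2) {
    warning(sprintf("curve %s: %d events; classifying by the last two",
                    events$curve_id[1], n))
    events <- events[order(events$position), ][(n - 1):n, ]
  }
  sep <- abs(diff(sort(events$position)))
  if (sep <= simultaneity_window) "double_simultaneous" else "double_sequential"
}

#' Binding probability of a curve set
#'
#' The fraction of curves showing at least one specific unbinding event
#' (e.g. 200 event-bearing curves out of 2000 measured is a binding
#' probability of 10%). Sequential double ruptures contribute a single count
#' (the curve either bound or it did not). Also reports the double-bond
#' fraction for on-rate analysis, with Clopper-Pearson (exact binomial)
#' confidence intervals.
#'
#' Double bonds are counted from the binding class (two resolved ruptures)
#' and, when `double_force_cutoff` is given, also from single-drop curves
#' whose final rupture force exceeds the cutoff -- the high-force (second
#' Gaussian) population produced when both bonds break within the detector's
#' resolution, which a pure event count would miss.
#'
#' @param x a [curve_set()], a `curve_experiment` cell, or a list of
#'   per-curve event data frames.
#' @param snr_threshold passed to [detect_events()] when `x` contains curves.
#' @param conf_level confidence level for the binomial CI.
#' @param double_force_cutoff optional force (pN) above which a single-drop
#'   curve is counted as a simultaneous double rupture (typically
#'   mu1 + 2*sigma1 from [fit_bimodal()]).
#' @param ... passed to [detect_events()].
#' @return A one-row data frame: `n_curves`, `n_bound`, `n_double`,
#'   `probability`, `ci_lo`, `ci_hi`, `double_fraction`, `dwell_time_s`.
#' @export
binding_probability <- function(x, snr_threshold = 2, conf_level = 0.95,
                                double_force_cutoff = NULL, ...) {
  if (inherits(x, "curve_set")) {
    events <- lapply(x$curves, detect_events, snr_threshold = snr_threshold, ...)
    dwell <- x$dwell_time_s
  } else if (is.list(x) && length(x) > 0 && all(vapply(x, is.data.frame, logical(1)))) {
    events <- x
    dwell <- NA_real_
  } else {
    fs_abort("`x` must be a curve_set or a non-empty list of event tables",
             class = "forcespec_invalid_argument")
  }
  fs_check(length(events) >= 1, "empty curve set")
  classes <- vapply(events, function(e) suppressWarnings(classify_curve(e)),
                    character(1))
  n <- length(classes)
  n_bound <- sum(classes != "none")
  is_double <- classes %in% c("double_simultaneous", "double_sequential")
  if (!is.null(double_force_cutoff)) {
    high <- vapply(events, function(e) {
      nrow(e) > 0 && max(e$force) >= double_force_cutoff
    }, logical(1))
    is_double <- is_double | high
  }
  n_double <- sum(is_double)
  ci <- stats::binom.test(n_bound, n, conf.level = conf_level)$conf.int
  data.frame(n_curves = n, n_bound = n_bound, n_double = n_double,
             probability = n_bound / n, ci_lo = ci[1], ci_hi = ci[2],
             double_fraction = n_double / n, dwell_time_s = dwell)
}

#' Export detected events for a curve set as one table
#'
#' Runs detection (and optionally elasticity annotation) on every curve and
#' binds the per-curve tables, adding the curve's binding class.
#'
#' @param cs a [curve_set()].
#' @param annotate if `TRUE`, add loading-rate columns via
#'   [annotate_loading_rates()].
#' @param final_only keep only the last rupture of each curve (the
#'   convention for kinetic analysis: a sequential pair contributes its final,
#'   single-remaining-bond rupture).
#' @param ... passed to [detect_events()].
#' @return A data frame of events across the set (possibly zero rows).
#' @export
detect_events_set <- function(cs, annotate = TRUE, final_only = FALSE, ...) {
  fs_check(inherits(cs, "curve_set"), "`cs` must be a curve_set")
  tabs <- lapply(cs$curves, function(cur) {
    ev <- detect_events(cur, ...)
    if (nrow(ev) == 0) return(NULL)
    ev$class <- suppressWarnings(classify_curve(ev))
    if (final_only) ev <- ev[nrow(ev), , drop = FALSE]
    if (annotate) ev <- suppressWarnings(annotate_loading_rates(cur, ev))
    if (nrow(ev) == 0) return(NULL)
    ev
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (length(tabs) == 0) {
    return(data.frame(order = integer(0), force = numeric(0),
                      position = numeric(0), noise_sd = numeric(0),
                      curve_id = character(0), class = character(0)))
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
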