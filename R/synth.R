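#' Simulation configuration for the force-curve generator
#'
#' Collects the ground-truth kinetic and mechanical parameters of the
#' Monte-Carlo experiment generator. Defaults reproduce the canonical
#' measurement conditions: nominal cantilever 10 pN/nm (0.01 N/m), 2000
#' samples per curve, 3000 nm z-range, retraction velocities giving loading
#' rates of order 50-5000 pN/s, thermal force noise of a few pN, and
#' anti-HER2 nanobody/BT-474-like bond kinetics (koff = 0.23 1/s,
#' xbeta = 1.23 nm).
#'
#' @param koff_true single-bond zero-force off-rate, 1/s.
#' @param xbeta_true barrier width, nm.
#' @param kon2_true second-bond formation rate, 1/s.
#' @param bind_sat_A saturated binding probability A (fraction in \[0,1\]).
#' @param lag_t0 lag time t0 of the association model, s.
#' @param tau_on characteristic association time tau, s.
#' @param double_sat saturated double-bond probability (fraction of all
#'   curves; doubles are a subset of bound curves, so `double_sat` must not
#'   exceed what `bind_sat_A` and the two time constants allow).
#' @param kc cantilever spring constant, pN/nm.
#' @param linker_contour PEG cross-linker contour length, nm.
#' @param linker_persistence WLC persistence length, nm.
#' @param membrane_stiffness linear membrane-tether stiffness, pN/nm.
#' @param contact_stiffness cell indentation stiffness, pN/nm.
#' @param force_limit approach force setpoint (compressive), pN.
#' @param noise_sd thermal force noise sd, pN.
#' @param retract_velocity nm/s.
#' @param z_range piezo travel, nm.
#' @param samples_per_curve samples across the approach+retract ramps.
#' @param n_curves curves per condition.
#' @param seed integer master seed; identical seed + config give
#'   bit-identical output.
#' @param load_sharing `"shared"` or `"full"` (see
#'   [sample_double_bond_forces()]).
#' @param kbt thermal energy, pN nm.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(koff_true = 0.23,
                              xbeta_true = 1.23,
                              kon2_true = 17,
                              bind_sat_A = 0.13,
                              lag_t0 = 0,
                              tau_on = 0.0263,
                              double_sat = 0.04,
                              kc = 10,
                              linker_contour = 6,
                              linker_persistence = 0.38,
                              membrane_stiffness = 0.35,
                              contact_stiffness = 2,
                              force_limit = 50,
                              noise_sd = 3,
                              retract_velocity = 3000,
                              z_range = 3000,
                              samples_per_curve = 2000,
                              n_curves = 1000,
                              seed = 1L,
                              load_sharing = c("shared", "full"),
                              kbt = KBT_ROOM) {
  load_sharing <- match.arg(load_sharing)
  for (nm in c("koff_true", "xbeta_true", "kon2_true", "tau_on",
               "kc", "linker_contour", "linker_persistence",
               "membrane_stiffness", "contact_stiffness", "force_limit",
               "noise_sd", "retract_velocity", "z_range", "kbt")) {
    check_pos(get(nm), nm)
  }
  fs_check(bind_sat_A >= 0 && bind_sat_A <= 1, "`bind_sat_A` must be in [0,1]")
  fs_check(double_sat >= 0 && double_sat <= 1, "`double_sat` must be in [0,1]")
  fs_check(lag_t0 >= 0, "`lag_t0` must be >= 0")
  fs_check(samples_per_curve >= 2, "`samples_per_curve` must be >= 2")
  fs_check(n_curves >= 1, "`n_curves` must be >= 1")
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> koff = %.3g 1/s, xbeta = %.3g nm, kon2 = %.3g 1/s\n",
    "  A = %.3g, tau_on = %.4g s, kc = %.3g pN/nm, v = %.4g nm/s, noise %.2g pN\n",
    "  %d curves x %d samples, z-range %.0f nm, load sharing '%s', seed %d\n"),
    x$koff_true, x$xbeta_true, x$kon2_true, x$bind_sat_A, x$tau_on, x$kc,
    x$retract_velocity, x$noise_sd, x$n_curves, x$samples_per_curve,
    x$z_range, x$load_sharing, as.integer(x$seed)))
  invisible(x)
}

# Precompute force-vs-piezo branches of the elastic system.
# Single bond: z(F) = x_wlc(F) + F/km + F/kc.
# Double bond (shared load): two identical linker+tether springs in parallel,
# each carrying F/2: z(F) = x_wlc(F/2) + (F/2)/km + F/kc.
# Under "full" sharing each bond bears the full load and the double branch
# coincides with the single one.
# Returns approx-functions F(z) per branch and dF/dz for loading rates.
elastic_branches <- function(config, f_max = 2500, n_grid = 600) {
  fgrid <- seq(0, f_max, length.out = n_grid)
  x1 <- wlc_extension(fgrid, config$linker_contour, config$linker_persistence,
                      config$kbt)
  z1 <- x1 + fgrid / config$membrane_stiffness + fgrid / config$kc
  if (config$load_sharing == "shared") {
    x2 <- wlc_extension(fgrid / 2, config$linker_contour,
                        config$linker_persistence, config$kbt)
    z2 <- x2 + (fgrid / 2) / config$membrane_stiffness + fgrid / config$kc
  } else {
    z2 <- z1
  }
  list(
    f_of_z1 = stats::approxfun(z1, fgrid, rule = 2),
    f_of_z2 = stats::approxfun(z2, fgrid, rule = 2),
    # instantaneous total stiffness dF/dz per branch
    k_of_z1 = stats::approxfun(z1[-1], diff(fgrid) / diff(z1), rule = 2),
    k_of_z2 = stats::approxfun(z2[-1], diff(fgrid) / diff(z2), rule = 2)
  )
}

#' Simulate one AFM force-distance curve
#'
#' Assembles an approach ramp to the compressive force setpoint, an optional
#' constant-contact dwell, and a retract trace. With probability given by the
#' saturating association model P(t) = A*(1 - exp(-(t - t0)/tau)) at the
#' curve's dwell time a bond is formed, and (given binding) a second bond with
#' probability double_sat*(1 - exp(-kon2*t)). Bound retractions stretch the
#' nonlinear linker + membrane system; ruptures are drawn from Bell kinetics
#' integrated along the actual force trajectory (time-inhomogeneous survival,
#' sampled by inverting the cumulative hazard accumulated over the trace).
#' Gaussian force noise of sd `noise_sd` is added throughout.
#'
#' Ground truth (class, true rupture forces/positions, instantaneous
#' stiffness-based loading rates) is stored in the curve's `truth` sidecar
#' field, which the file writer never serialises into the curve file.
#'
#' @param config a [simulation_config()].
#' @param dwell_time requested tip-surface dwell time, s. Realised as contact
#'   travel (indentation at the force setpoint) plus an explicit dwell
#'   segment when the requested time exceeds the travel time.
#' @param seed integer seed for this curve.
#' @param branches internal: precomputed [elastic_branches()] to reuse across
#'   curves.
#' @return A [force_curve()] with `truth` sidecar.
#' @export
simulate_force_curve <- function(config, dwell_time = 0.05, seed = NULL,
                                 branches = NULL) {
  fs_check(inherits(config, "simulation_config"),
           "`config` must be a simulation_config")
  fs_check(dwell_time >= 0, "`dwell_time` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(branches)) branches <- elastic_branches(config)
  v <- config$retract_velocity
  kbt <- config$kbt
  a <- config$xbeta_true / kbt
  s <- if (config$load_sharing == "shared") 0.5 else 1
  d <- config$force_limit / config$contact_stiffness  # indentation depth, nm
  n_ramp <- config$samples_per_curve
  n_app <- floor(n_ramp / 2)
  n_ret <- n_ramp - n_app
  fs_samp <- n_app * v / (config$z_range + d)  # sampling rate, Hz

  z_app <- seq(config$z_range, -d, length.out = n_app)
  z_ret <- seq(-d, config$z_range, length.out = n_ret)
  dz <- z_ret[2] - z_ret[1]

  t_travel <- 2 * d / v
  n_dwell <- 0L
  if (dwell_time > t_travel)
    n_dwell <- as.integer(round((dwell_time - t_travel) * fs_samp))
  t_d <- t_travel + n_dwell / fs_samp  # realised dwell time

  # association model
  p_bind <- if (t_d > config$lag_t0) {
    config$bind_sat_A * (1 - exp(-(t_d - config$lag_t0) / config$tau_on))
  } else 0
  bound <- stats::runif(1) < p_bind
  # double-bond formation follows its own pseudo-first-order law in the
  # marginal over curves, P2(t) = double_sat * (1 - exp(-kon2*t)); doubles
  # are a subset of bound curves, so the conditional probability is P2/P1
  p_double <- config$double_sat * (1 - exp(-config$kon2_true * t_d))
  double <- bound && stats::runif(1) < min(1, p_double / max(p_bind, 1e-12))

  f_app <- ifelse(z_app < 0, config$contact_stiffness * z_app, 0)
  f_dwell <- rep(-config$force_limit, n_dwell)
  f_ret <- ifelse(z_ret < 0, config$contact_stiffness * z_ret, 0)

  truth <- list(bound = bound, class = "none", dwell_time = t_d,
                rupture_forces = numeric(0), rupture_z = numeric(0),
                loading_rates = numeric(0))
  if (bound) {
    teth <- z_ret >= 0
    zt <- z_ret[teth]
    dt <- dz / v
    draw_rupture <- function(haz, from = 1L) {
      # first index (>= from) at which the cumulative hazard crosses Exp(1)
      ch <- cumsum(haz[from:length(haz)]) * dt
      e <- stats::rexp(1)
      i <- which(ch >= e)
      if (length(i) == 0) length(haz) else from + i[1] - 1L
    }
    if (!double) {
      fb <- branches$f_of_z1(zt)
      i1 <- draw_rupture(config$koff_true * exp(a * fb))
      f_bound <- fb
      f_bound[seq_along(f_bound) > i1] <- 0
      truth$class <- "single"
      truth$rupture_forces <- fb[i1]
      truth$rupture_z <- zt[i1]
      truth$loading_rates <- v * branches$k_of_z1(zt[i1])
    } else {
      fb2 <- branches$f_of_z2(zt)
      i1 <- draw_rupture(2 * config$koff_true * exp(s * a * fb2))
      fb1 <- branches$f_of_z1(zt)
      i2 <- draw_rupture(config$koff_true * exp(a * fb1), from = i1)
      f_bound <- fb2
      if (i2 - i1 <= 1L) {
        # both ruptures within one sampling interval: simultaneous
        f_bound[seq_along(f_bound) > i1] <- 0
        truth$class <- "double_simultaneous"
        truth$rupture_forces <- fb2[i1]
        truth$rupture_z <- zt[i1]
        truth$loading_rates <- v * branches$k_of_z2(zt[i1])
      } else {
        sel <- seq_along(f_bound) > i1
        f_bound[sel] <- fb1[sel]
        f_bound[seq_along(f_bound) > i2] <- 0
        truth$class <- "double_sequential"
        truth$rupture_forces <- c(fb2[i1], fb1[i2])
        truth$rupture_z <- c(zt[i1], zt[i2])
        truth$loading_rates <- v * c(branches$k_of_z2(zt[i1]),
                                     branches$k_of_z1(zt[i2]))
      }
    }
    f_ret[teth] <- f_bound
  }

  z <- c(z_app, rep(-d, n_dwell), z_ret)
  f <- c(f_app, f_dwell, f_ret)
  if (config$noise_sd > 0) f <- f + stats::rnorm(length(f), 0, config$noise_sd)
  segment <- c(rep("approach", n_app), rep("dwell", n_dwell),
               rep("retract", n_ret))
  force_curve(z, f, segment, kc = config$kc, velocity = v,
              sampling_rate = fs_samp,
              curve_id = sprintf("sim_seed%s", format(seed %||% "NA")),
              truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full factorial force-spectroscopy experiment
#'
#' One [curve_set()] per (retraction velocity, dwell time) cell, `n_curves`
#' curves per cell. Per-curve seeds are derived deterministically from
#' `config$seed`, so identical inputs give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param velocity_grid retraction velocities, nm/s (non-empty).
#' @param dwell_grid dwell times, s (non-empty).
#' @return An object of class `curve_experiment`: list of cells, each a
#'   [curve_set()] carrying a `velocity` attribute.
#' @export
simulate_experiment <- function(config,
                                velocity_grid = config$retract_velocity,
                                dwell_grid = 0.05) {
  fs_check(inherits(config, "simulation_config"),
           "`config` must be a simulation_config")
  fs_check(length(velocity_grid) >= 1 && length(dwell_grid) >= 1,
           "velocity and dwell grids must be non-empty")
  fs_check(all(velocity_grid > 0) && all(dwell_grid >= 0),
           "velocities must be > 0 and dwell times >= 0")
  cells <- list()
  cell_idx <- 0L
  for (v in velocity_grid) {
    cfg <- config
    cfg$retract_velocity <- v
    branches <- elastic_branches(cfg)
    for (dw in dwell_grid) {
      cell_idx <- cell_idx + 1L
      seeds <- (as.integer(config$seed) + 1000003 * cell_idx +
                  seq_len(config$n_curves)) %% .Machine$integer.max
      curves <- lapply(seq_len(config$n_curves), function(i) {
        cur <- simulate_force_curve(cfg, dwell_time = dw, seed = seeds[i],
                                    branches = branches)
        cur$curve_id <- sprintf("v%g_d%g_%04d", v, dw, i)
        cur
      })
      cs <- curve_set(curves, condition = sprintf("v%g_d%g", v, dw),
                      dwell_time_s = dw)
      attr(cs, "velocity") <- v
      cells[[sprintf("v%g_d%g", v, dw)]] <- cs
    }
  }
  structure(list(cells = cells, config = config), class = "curve_experiment")
}

#' @export
print.curve_experiment <- function(x, ...) {
  cat(sprintf("<curve_experiment> %d cells x %d curves\n",
              length(x$cells), x$config$n_curves))
  invisible(x)
}
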