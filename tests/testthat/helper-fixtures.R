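# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# canonical single-bond truth: anti-HER2 nanobody / BT-474-like kinetics
canonical_bell <- function() bell_parameters(koff = 0.23, xbeta = 1.23)

# a flat-baseline retract trace with one planted rupture: force ramps
# linearly up to `force` pN over `ramp_nm` and drops to baseline at `z_rup`
make_step_curve <- function(force = 50, z_rup = 300, noise_sd = 3,
                            ramp_nm = 100, n = 1200, z_max = 3000,
                            seed = NULL, kc = 10, velocity = 3000) {
  if (!is.null(seed)) set.seed(seed)
  z_app <- seq(z_max, 0, length.out = 50)
  f_app <- rep(0, 50)
  z_ret <- seq(0, z_max, length.out = n)
  f_ret <- rep(0, n)
  on_ramp <- z_ret >= (z_rup - ramp_nm) & z_ret <= z_rup
  f_ret[on_ramp] <- force * (z_ret[on_ramp] - (z_rup - ramp_nm)) / ramp_nm
  f <- c(f_app, f_ret)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  force_curve(c(z_app, z_ret), f,
              c(rep("approach", 50), rep("retract", n)),
              kc = kc, velocity = velocity, sampling_rate = 1000,
              curve_id = sprintf("step_%g", force))
}

# noise-only retract trace (no planted rupture)
make_noise_curve <- function(noise_sd = 3, seed = NULL, n = 1200) {
  make_step_curve(force = 0, ramp_nm = 1e-6, noise_sd = noise_sd,
                  seed = seed, n = n)
}

# pure worm-like-chain stretch curve (no membrane spring): retract force
# follows the WLC through the cantilever up to f_max, then ruptures
make_wlc_curve <- function(lc = 50, lp = 0.38, kc = 10, f_max = 30,
                           n = 400, z_max = 200, velocity = 3000) {
  fgrid <- seq(0, f_max, length.out = 1000)
  zg <- wlc_extension(fgrid, lc, lp) + fgrid / kc
  f_of_z <- stats::approxfun(zg, fgrid, rule = 2)
  z_ret <- seq(0, z_max, length.out = n)
  f_ret <- ifelse(z_ret <= max(zg), f_of_z(z_ret), 0)
  z_app <- seq(z_max, 0, length.out = 20)
  force_curve(c(z_app, z_ret), c(rep(0, 20), f_ret),
              c(rep("approach", 20), rep("retract", n)),
              kc = kc, velocity = velocity, sampling_rate = 1000,
              curve_id = "wlc_fixture")
}

# event table drawn straight from the Bell sampler (bypassing curves)
make_bell_events <- function(bell, rates, n_per_rate, seed = 1,
                             noise_sd = 0) {
  set.seed(seed)
  f <- unlist(lapply(rates, function(r)
    sample_rupture_forces(bell, r, n_per_rate)))
  r <- rep(rates, each = n_per_rate)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(force = f, loading_rate = r,
             noise_sd = if (noise_sd > 0) noise_sd else 0.1)
}
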