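# Monte-Carlo generator: Bell samplers, two-bond Markov chain, force curves

test_that("inverse-CDF sampler matches the analytic density and mode", {
  b <- canonical_bell()
  r <- 1000
  f <- sample_rupture_forces(b, r, 1e5, seed = 1)
  # closed-form most probable force with kBT = 4.114 pN nm
  fstar <- (4.114 / 1.23) * log(r * 1.23 / (0.23 * 4.114))
  expect_equal(bell_mode(b, r), fstar, tolerance = 1e-12)
  expect_equal(fstar, 23.98, tolerance = 1e-3)
  d <- stats::density(f)
  expect_equal(d$x[which.max(d$y)], fstar, tolerance = 0.05)
  # Kolmogorov-Smirnov distance against numerical integration of p(F)
  grid <- seq(0, max(f) + 5, length.out = 4000)
  dens <- bell_density(grid, b, r)
  cdf_num <- cumsum(c(0, diff(grid) * (head(dens, -1) + tail(dens, -1)) / 2))
  cdf_at <- stats::approxfun(grid, cdf_num / max(cdf_num), rule = 2)
  xs <- sort(f); emp <- seq_along(xs) / length(xs)
  ks <- max(abs(emp - cdf_at(xs)), abs(emp - 1 / length(xs) - cdf_at(xs)))
  expect_lt(ks, 0.01)
})

test_that("a vanishing barrier under load gives near-zero rupture forces", {
  b <- bell_parameters(koff = 0.23, xbeta = 1000)
  f <- sample_rupture_forces(b, 1000, 1000, seed = 2)
  expect_lt(max(f), 0.5)
})

test_that("samplers validate their arguments", {
  b <- canonical_bell()
  expect_error(sample_rupture_forces(b, -5, 10), class = "forcespec_error")
  expect_error(sample_rupture_forces(b, 100, 0), class = "forcespec_error")
  expect_error(bell_parameters(-1, 1), class = "forcespec_error")
  expect_error(sample_double_bond_forces(b, 100, 10, load_sharing = "odd"))
})

test_that("two-bond zero-load lifetime averages 1.5/koff", {
  koff <- 0.23
  lt <- sample_two_bond_lifetimes(koff, 1e5, seed = 3)
  se <- stats::sd(lt) / sqrt(length(lt))
  expect_lt(abs(mean(lt) - 1.5 / koff), 3 * se)
})

test_that("double-bond rupture modes exceed the single-bond mode at the same rate", {
  b <- canonical_bell()
  for (ls in c("shared", "full")) {
    fd <- sample_double_bond_forces(b, 1000, 2e4, seed = 4, load_sharing = ls)
    dd <- stats::density(fd)
    mode_d <- dd$x[which.max(dd$y)]
    expect_gt(mode_d, bell_mode(b, 1000))
  }
})

test_that("samplers and simulator are bit-reproducible under a seed", {
  b <- canonical_bell()
  expect_identical(sample_rupture_forces(b, 500, 100, seed = 9),
                   sample_rupture_forces(b, 500, 100, seed = 9))
  expect_identical(sample_double_bond_forces(b, 500, 100, seed = 9),
                   sample_double_bond_forces(b, 500, 100, seed = 9))
  cfg <- simulation_config(n_curves = 2, samples_per_curve = 400, seed = 5)
  c1 <- simulate_force_curve(cfg, 0.05, seed = 11)
  c2 <- simulate_force_curve(cfg, 0.05, seed = 11)
  expect_identical(c1$force, c2$force)
  e1 <- simulate_experiment(cfg, 3000, c(0.02, 0.05))
  e2 <- simulate_experiment(cfg, 3000, c(0.02, 0.05))
  expect_identical(e1$cells[[1]]$curves[[1]]$force,
                   e2$cells[[1]]$curves[[1]]$force)
})

test_that("simulated curves carry consistent structure and truth sidecars", {
  cfg <- simulation_config(seed = 5)
  cur <- simulate_force_curve(cfg, dwell_time = 0.05, seed = 7)
  expect_s3_class(cur, "force_curve")
  expect_length(cur$force, length(cur$z))
  expect_true(all(c("approach", "retract") %in% cur$segment))
  expect_true(cur$truth$class %in%
                c("none", "single", "double_simultaneous", "double_sequential"))
  # unbound configuration never plants a rupture
  cfg0 <- simulation_config(bind_sat_A = 0, seed = 5)
  cur0 <- simulate_force_curve(cfg0, 0.05, seed = 3)
  expect_identical(cur0$truth$class, "none")
  expect_identical(nrow(detect_events(cur0)), 0L)
})

test_that("noiseless planted ruptures are recovered exactly by detection", {
  cfg <- simulation_config(bind_sat_A = 1, tau_on = 1e-4, double_sat = 0,
                           noise_sd = 1e-9, force_limit = 80, seed = 1)
  for (s in 1:3) {
    cur <- simulate_force_curve(cfg, 0.05, seed = s)
    ev <- detect_events(cur)
    expect_identical(nrow(ev), 1L)
    expect_equal(ev$force, cur$truth$rupture_forces, tolerance = 1e-6)
    expect_equal(ev$position, cur$truth$rupture_z, tolerance = 1e-9)
  }
})

test_that("experiment grids are validated and factorial", {
  cfg <- simulation_config(n_curves = 3, samples_per_curve = 200, seed = 2)
  expect_error(simulate_experiment(cfg, numeric(0), 0.05),
               class = "forcespec_error")
  ex <- simulate_experiment(cfg, c(1000, 3000), c(0.02, 0.05))
  expect_length(ex$cells, 4)
  expect_length(ex$cells[[1]]$curves, 3)
})

test_that("binding fraction across a dwell grid follows the generating model", {
  cfg <- simulation_config(n_curves = 400, samples_per_curve = 400,
                           noise_sd = 1e-9, double_sat = 0, seed = 3)
  ex <- simulate_experiment(cfg, 3000, c(0.02, 0.05, 0.1, 0.3))
  for (cell in ex$cells) {
    bound <- vapply(cell$curves, function(cu) cu$truth$bound, logical(1))
    t_d <- cell$curves[[1]]$truth$dwell_time
    p_model <- cfg$bind_sat_A * (1 - exp(-t_d / cfg$tau_on))
    se <- sqrt(p_model * (1 - p_model) / length(bound))
    expect_lt(abs(mean(bound) - p_model), 4 * se + 1e-12)
  }
})
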