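# WLC fitting, effective spring constants, loading rates

test_that("series compliance combines cantilever and linker stiffness", {
  expect_equal(effective_spring_constant(10, 10), 5)
  # rigid-linker limit -> cantilever stiffness
  expect_equal(effective_spring_constant(10, 1e9), 10, tolerance = 1e-7)
  # nominal cantilever with a soft molecular spring: r ~ 1000 pN/s at 3000 nm/s
  keff <- effective_spring_constant(10, 0.35)
  expect_equal(keff, 0.3382, tolerance = 1e-3)
  expect_equal(loading_rate(3000, keff), 1014.5, tolerance = 1e-3)
  # symmetry and upper bound
  expect_equal(effective_spring_constant(3, 7), effective_spring_constant(7, 3))
  expect_lt(effective_spring_constant(3, 7), 3)
  expect_error(effective_spring_constant(-1, 2), class = "forcespec_error")
})

test_that("loading rate is velocity times effective stiffness", {
  expect_identical(loading_rate(3000, 1), 3000)
  expect_identical(loading_rate(2 * 3000, 1), 2 * loading_rate(3000, 1))
  expect_error(loading_rate(0, 1), class = "forcespec_error")
})

test_that("WLC force law and its derivative are mutually consistent", {
  x <- seq(1, 45, by = 1)
  f <- wlc_force(x, lc = 50, lp = 0.38)
  expect_true(all(diff(f) > 0))
  # analytic stiffness matches numeric differentiation
  k_num <- (wlc_force(x + 1e-6, 50, 0.38) - wlc_force(x - 1e-6, 50, 0.38)) / 2e-6
  expect_equal(wlc_stiffness(x, 50, 0.38), k_num, tolerance = 1e-6)
  # inverse map round-trips
  expect_equal(wlc_extension(f, 50, 0.38), x, tolerance = 1e-8)
})

test_that("WLC fit recovers known parameters from a noiseless stretch", {
  cur <- make_wlc_curve(lc = 50, lp = 0.38, f_max = 30)
  ret <- cur$segment == "retract"
  i_rup <- max(which(cur$force[ret] > 1))
  event <- data.frame(force = cur$force[ret][i_rup],
                      position = cur$z[ret][i_rup], noise_sd = 0.1)
  fit <- fit_wlc(cur, event)
  expect_identical(fit$fit_status, "wlc")
  expect_equal(fit$lc, 50, tolerance = 0.02)
  expect_equal(fit$lp, 0.38, tolerance = 0.05)
  # stiffness at rupture matches the analytic value on the true chain
  k_true <- wlc_stiffness(wlc_extension(event$force, 50, 0.38), 50, 0.38)
  expect_equal(fit$kl, k_true, tolerance = 0.05)
})

test_that("fitted stiffness grows with rupture force on the same chain", {
  cur <- make_wlc_curve(lc = 50, lp = 0.38, f_max = 30)
  ret <- cur$segment == "retract"
  kls <- vapply(c(10, 20, 29), function(fr) {
    i <- which.min(abs(cur$force[ret] - fr))
    ev <- data.frame(force = cur$force[ret][i], position = cur$z[ret][i],
                     noise_sd = 0.1)
    fit_wlc(cur, ev)$kl
  }, numeric(1))
  expect_true(all(diff(kls) > 0))
})

test_that("assigned loading rates track the generator's instantaneous truth", {
  cfg <- simulation_config(bind_sat_A = 1, tau_on = 1e-4, double_sat = 0,
                           noise_sd = 1e-9, seed = 1)
  rel <- c()
  for (s in 1:25) {
    cur <- simulate_force_curve(cfg, 0.05, seed = s)
    ev <- detect_events(cur)
    if (nrow(ev) != 1) next
    ann <- annotate_loading_rates(cur, ev)
    rel <- c(rel, ann$loading_rate / cur$truth$loading_rates[1])
  }
  expect_gt(length(rel), 15)
  expect_true(all(abs(rel - 1) < 0.15))
})

test_that("loading rates across a velocity sweep span the expected range", {
  cfg <- simulation_config(bind_sat_A = 1, tau_on = 1e-4, double_sat = 0,
                           n_curves = 30, seed = 2)
  ex <- simulate_experiment(cfg, velocity_grid = c(300, 3000, 15000),
                            dwell_grid = 0.03)
  ev <- do.call(rbind, lapply(ex$cells, detect_events_set, final_only = TRUE))
  expect_gt(nrow(ev), 40)
  expect_gt(min(ev$loading_rate), 30)
  expect_lt(max(ev$loading_rate), 10000)
  expect_gt(max(ev$loading_rate) / min(ev$loading_rate), 10)
})

test_that("events with too few stretch samples are signalled and droppable", {
  cur <- make_step_curve(50, z_rup = 300, ramp_nm = 3, noise_sd = 0, n = 300)
  ret <- cur$segment == "retract"
  i <- which.max(cur$force[ret])
  ev <- data.frame(force = cur$force[ret][i], position = cur$z[ret][i],
                   noise_sd = 0.1)
  expect_error(fit_wlc(cur, ev), class = "forcespec_fit_failure")
})
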