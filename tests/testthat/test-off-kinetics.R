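# Force PDFs, bimodal decomposition, gating, Bell-Evans ML, Markov reduction

test_that("the summed-Gaussian PDF conserves event count and peaks correctly", {
  ev1 <- data.frame(force = 50, noise_sd = 3)
  pdf1 <- build_pdf(ev1, grid_step = 0.05)
  tz <- function(p) sum(diff(p$grid) * (head(p$density, -1) + tail(p$density, -1)) / 2)
  expect_equal(tz(pdf1), 1, tolerance = 1e-6)
  expect_equal(pdf1$grid[which.max(pdf1$density)], 50, tolerance = 0.06)

  set.seed(4)
  ev <- data.frame(force = rnorm(200, 40, 6), noise_sd = runif(200, 2, 4))
  pdf <- build_pdf(ev, grid_step = 0.1)
  expect_equal(tz(pdf), 200, tolerance = 0.01)
  expect_true(all(pdf$density >= 0))
  # duplicating events doubles the integral, leaves the normalised shape
  pdf2 <- build_pdf(rbind(ev, ev), grid_step = 0.1)
  expect_equal(tz(pdf2), 400, tolerance = 0.02)
  expect_equal(pdf2$density / pdf2$n_events, pdf$density / pdf$n_events,
               tolerance = 1e-9)
  expect_error(build_pdf(ev[0, ]), class = "forcespec_error")
})

test_that("the canonical two-population fixture gives a bimodal PDF", {
  b <- canonical_bell()
  set.seed(9)
  f1 <- sample_rupture_forces(b, 1000, 700)
  f2 <- sample_double_bond_forces(b, 1000, 300)
  ev <- data.frame(force = c(f1, f2), noise_sd = 3)
  pdf <- build_pdf(ev)
  # modes of the generating populations
  m1 <- bell_mode(b, 1000)
  m2 <- predict_double_bond(b, 1000)[["1000"]]$mode
  d1 <- pdf$density[which.min(abs(pdf$grid - m1))]
  mid <- pdf$density[which.min(abs(pdf$grid - (m1 + m2) / 2))]
  d2 <- pdf$density[which.min(abs(pdf$grid - m2))]
  expect_gt(d1, mid)
  expect_gt(d2, 0.5 * mid)
  bim <- fit_bimodal(ev)
  # the lower mixture mean tracks the single-bond mode; the upper component
  # sits clearly above it, between the two generating modes (the populations
  # are skewed and overlap, so the mixture mean underestimates the upper
  # mode itself)
  expect_lt(abs(bim$mu1 - m1), 4)
  expect_gt(bim$mu2, bim$mu1 + 4)
  expect_lt(bim$mu2, m2 + 4)
})

test_that("mixture recovery: 70/30 Gaussians are resolved within 1 pN", {
  set.seed(11)
  f <- c(rnorm(1400, 30, 5), rnorm(600, 60, 7))
  bim <- fit_bimodal(f)
  expect_lt(abs(bim$mu1 - 30), 1)
  expect_lt(abs(bim$mu2 - 60), 1)
  expect_lt(abs(bim$w1 - 0.7), 0.05)
  expect_equal(bim$w1 + bim$w2, 1, tolerance = 1e-9)
  expect_lt(bim$mu1, bim$mu2)
})

test_that("degenerate mixtures are signalled", {
  expect_error(fit_bimodal(rnorm(10, 30, 5)), class = "forcespec_error")
})

test_that("the 2-sigma gate keeps the defined window and ~95% of a pure sample", {
  bim <- structure(list(mu1 = 30, sigma1 = 5, w1 = 0.5,
                        mu2 = 60, sigma2 = 5, w2 = 0.5),
                   class = "bimodal_fit")
  ev <- data.frame(force = seq(5, 70, by = 0.5), noise_sd = 3)
  g <- gate_single_bond(ev, bim)
  expect_true(all(g$force >= 20 & g$force <= 40))
  expect_identical(nrow(g), sum(ev$force >= 20 & ev$force <= 40))
  # normal-mass oracle: P(|Z| <= 2) = 0.9545
  set.seed(12)
  pure <- data.frame(force = rnorm(20000, 30, 5), noise_sd = 3)
  frac <- nrow(gate_single_bond(pure, bim)) / nrow(pure)
  expect_equal(frac, 0.9545, tolerance = 0.01)
})

test_that("gating reduces double-bond contamination on labelled fixtures", {
  b <- canonical_bell()
  set.seed(13)
  f1 <- sample_rupture_forces(b, 1000, 1400)
  f2 <- sample_double_bond_forces(b, 1000, 600)
  ev <- data.frame(force = c(f1, f2), noise_sd = 3,
                   is_double = rep(c(FALSE, TRUE), c(1400, 600)))
  bim <- fit_bimodal(ev)
  g <- gate_single_bond(ev, bim)
  expect_lt(mean(g$is_double), mean(ev$is_double))
})

test_that("closed-form most-probable-force line round-trips the parameters", {
  # independent oracle: F*(r) is linear in ln r with slope kbt/xbeta
  b <- canonical_bell()
  rates <- c(100, 500, 1000, 3000)
  fstar <- vapply(rates, function(r) bell_mode(b, r), numeric(1))
  co <- coef(lm(fstar ~ log(rates)))
  xbeta_hat <- 4.114 / co[2]
  koff_hat <- xbeta_hat / (4.114 * exp(co[1] / co[2]))
  expect_equal(unname(xbeta_hat), 1.23, tolerance = 1e-9)
  expect_equal(unname(koff_hat), 0.23, tolerance = 1e-9)
})

test_that("ML fit recovers truth from sampled events, with shrinking errors", {
  b <- canonical_bell()
  ev <- make_bell_events(b, c(100, 500, 1000, 3000), 500, seed = 21)
  fit <- fit_bell_ml(ev)
  expect_equal(fit$koff, 0.23, tolerance = 0.15)
  expect_equal(fit$xbeta, 1.23, tolerance = 0.05)
  # errors shrink roughly as 1/sqrt(n)
  ev_small <- make_bell_events(b, c(100, 500, 1000, 3000), 125, seed = 22)
  fit_small <- suppressWarnings(fit_bell_ml(ev_small))
  expect_gt(fit_small$se_log10_koff, 1.5 * fit$se_log10_koff)
  # fitted F* line is exposed for display
  expect_equal(attr(fit, "fstar")(1000), bell_mode(fit, 1000),
               tolerance = 1e-9)
})

test_that("ML fit with error convolution undoes measurement broadening", {
  b <- canonical_bell()
  ev <- make_bell_events(b, c(300, 1000, 3000), 800, seed = 23, noise_sd = 3)
  raw <- fit_bell_ml(ev)
  conv <- fit_bell_ml(ev, convolve_error = TRUE)
  # raw fit inflates koff; deconvolved fit lands near truth
  expect_gt(raw$koff / 0.23, 1.8)
  expect_equal(conv$koff, 0.23, tolerance = 0.2)
  expect_equal(conv$xbeta, 1.23, tolerance = 0.06)
})

test_that("gate-window truncation is corrected by the windowed likelihood", {
  b <- canonical_bell()
  ev <- make_bell_events(b, c(300, 1000, 3000), 1200, seed = 24, noise_sd = 3)
  g <- ev[ev$force >= 12 & ev$force <= 34, ]
  fit <- suppressWarnings(fit_bell_ml(g, convolve_error = TRUE,
                                      window = c(12, 34)))
  expect_equal(fit$koff, 0.23, tolerance = 0.25)
  expect_equal(fit$xbeta, 1.23, tolerance = 0.1)
})

test_that("two-bond reduction and lifetimes are exact closed forms", {
  expect_equal(two_bond_off_rate(1.5), 1)
  expect_equal(round(two_bond_off_rate(0.23), 2), 0.15)
  expect_equal(round(two_bond_off_rate(0.77), 2), 0.51)
  expect_equal(round(two_bond_off_rate(0.31), 2), 0.21)
  expect_equal(bond_lifetime(1), 1)
  expect_equal(round(bond_lifetime(0.23), 1), 4.3)
  expect_equal(round(bond_lifetime(0.31), 1), 3.2)
  expect_error(two_bond_off_rate(0), class = "forcespec_error")
  expect_error(bond_lifetime(-1), class = "forcespec_error")
})

test_that("master equation matches the stochastic two-bond simulator", {
  b <- canonical_bell()
  for (ls in c("shared", "full")) {
    pred <- predict_double_bond(b, c(500, 2000), load_sharing = ls)
    for (r in c("500", "2000")) {
      p <- pred[[r]]
      # density integrates to 1 and the mode exceeds the single-bond mode
      tz <- sum(diff(p$grid) * (head(p$density, -1) + tail(p$density, -1)) / 2)
      expect_equal(tz, 1, tolerance = 1e-6)
      expect_gt(p$mode, bell_mode(b, as.numeric(r)))
      # KS distance between simulator draws and master-equation CDF
      x <- sample_double_bond_forces(b, as.numeric(r), 1e4, seed = 31,
                                     load_sharing = ls)
      cdf_at <- approxfun(p$grid, p$cdf, rule = 2)
      xs <- sort(x); emp <- seq_along(xs) / length(xs)
      ks <- max(abs(emp - cdf_at(xs)), abs(emp - 1 / length(xs) - cdf_at(xs)))
      expect_lt(ks, 0.02)
    }
  }
})
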