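# Rupture-event detection, classification, binding probabilities

test_that("noise-only traces yield no events at SNR threshold 2", {
  for (s in 1:30) {
    expect_identical(nrow(detect_events(make_noise_curve(3, seed = s))), 0L)
  }
})

test_that("a planted 50 pN rupture in 3 pN noise is found near its position", {
  for (s in 1:10) {
    ev <- detect_events(make_step_curve(50, z_rup = 300, noise_sd = 3,
                                        seed = s))
    expect_identical(nrow(ev), 1L)
    expect_equal(ev$force, 50, tolerance = 0.25)   # relative: within ~4 sd
    expect_equal(ev$position, 300, tolerance = 0.05)
    expect_gt(ev$noise_sd, 1)
    expect_lt(ev$noise_sd, 6)
  }
})

test_that("noiseless planted ruptures are recovered exactly", {
  cur <- make_step_curve(50, z_rup = 300, noise_sd = 0)
  ev <- detect_events(cur)
  expect_identical(nrow(ev), 1L)
  # exactly the largest planted sample (the 50 pN peak lands between grid
  # points, so the discrete maximum is the truth)
  expect_equal(ev$force, max(cur$force), tolerance = 1e-12)
  expect_equal(ev$force, 50, tolerance = 0.05)
})

test_that("a 4 pN step in 3 pN noise stays below the SNR-2 threshold", {
  for (s in 1:10) {
    ev <- detect_events(make_step_curve(4, z_rup = 300, noise_sd = 3,
                                        seed = 100 + s))
    expect_identical(nrow(ev), 0L)
  }
})

test_that("recall is perfect at force/noise >= 5 and degrades below threshold", {
  recall_at <- function(force, n = 25) {
    mean(vapply(seq_len(n), function(s) {
      nrow(detect_events(make_step_curve(force, noise_sd = 3,
                                         seed = 200 + s))) >= 1
    }, logical(1)))
  }
  expect_identical(recall_at(15), 1)   # force/sigma = 5
  expect_identical(recall_at(40), 1)
  r8 <- recall_at(8)
  r5 <- recall_at(5)
  expect_lte(r5, r8)                   # monotone degradation
  expect_lt(r5, 1)
})

test_that("curves without a usable retract segment are rejected", {
  cur <- force_curve(1:100, rnorm(100), rep("approach", 100),
                     kc = 10, velocity = 3000, sampling_rate = 1000)
  expect_error(detect_events(cur), class = "forcespec_error")
})

test_that("binding classes follow event count and separation", {
  ev0 <- data.frame(order = integer(0), force = numeric(0),
                    position = numeric(0), noise_sd = numeric(0),
                    curve_id = character(0))
  expect_identical(classify_curve(ev0), "none")
  ev1 <- data.frame(order = 1, force = 30, position = 100, noise_sd = 3,
                    curve_id = "c")
  expect_identical(classify_curve(ev1), "single")
  ev2 <- data.frame(order = 1:2, force = c(30, 20), position = c(100, 200),
                    noise_sd = 3, curve_id = "c")
  expect_identical(classify_curve(ev2, simultaneity_window = 10),
                   "double_sequential")
  ev3 <- data.frame(order = 1:2, force = c(30, 20), position = c(100, 103),
                    noise_sd = 3, curve_id = "c")
  expect_identical(classify_curve(ev3), "double_simultaneous")
  ev4 <- rbind(ev2, data.frame(order = 3, force = 10, position = 290,
                               noise_sd = 3, curve_id = "c"))
  expect_warning(cl <- classify_curve(ev4), "last two")
  expect_identical(cl, "double_sequential")
})

test_that("binding probability counts bound curves over all curves", {
  mk <- function(n_events) {
    if (n_events == 0)
      return(data.frame(order = integer(0), force = numeric(0),
                        position = numeric(0), noise_sd = numeric(0),
                        curve_id = character(0)))
    data.frame(order = seq_len(n_events), force = 30,
               position = 100 * seq_len(n_events), noise_sd = 3,
               curve_id = "c")
  }
  # 200 event-bearing curves of 2000 -> 10%
  evs <- c(replicate(200, mk(1), simplify = FALSE),
           replicate(1800, mk(0), simplify = FALSE))
  bp <- binding_probability(evs)
  expect_identical(bp$probability, 0.1)
  expect_identical(bp$n_bound, 200L)
  # edge cases: none bound, all bound
  expect_identical(binding_probability(replicate(50, mk(0), simplify = FALSE))$probability, 0)
  expect_identical(binding_probability(replicate(50, mk(1), simplify = FALSE))$probability, 1)
  # sequential curves count once; doubles tracked separately
  evs2 <- c(replicate(5, mk(2), simplify = FALSE),
            replicate(5, mk(0), simplify = FALSE))
  bp2 <- binding_probability(evs2)
  expect_identical(bp2$probability, 0.5)
  expect_identical(bp2$double_fraction, 0.5)
  # permutation invariance
  set.seed(1)
  bp3 <- binding_probability(sample(evs2))
  expect_identical(bp3$probability, bp2$probability)
  # binomial CI brackets the estimate
  expect_lt(bp2$ci_lo, 0.5); expect_gt(bp2$ci_hi, 0.5)
  expect_error(binding_probability(list()), class = "forcespec_error")
})

test_that("high-force cutoff counts unresolved simultaneous doubles", {
  mk1 <- function(force) data.frame(order = 1, force = force, position = 100,
                                    noise_sd = 3, curve_id = "c")
  evs <- c(replicate(6, mk1(25), simplify = FALSE),
           replicate(4, mk1(45), simplify = FALSE))
  expect_identical(binding_probability(evs)$double_fraction, 0)
  expect_identical(
    binding_probability(evs, double_force_cutoff = 35)$double_fraction, 0.4)
})
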