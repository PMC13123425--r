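test_that("rupture-force sampling matches the closed-form distribution", {
  cases <- list(list(p = bell_alone(), r = 10),
                list(p = bell_wt(), r = 30),
                list(p = bell_evans_params(0.5, 0, kBT = 4.114), r = 5))
  for (cs in cases) {
    f <- simulate_rupture_forces(cs$p, cs$r, 1000, seed = 21)
    ks <- suppressWarnings(stats::ks.test(f, function(q) prupture(q, cs$p, cs$r)))
    expect_gt(ks$p.value, 0.01)
    # quantile / cdf round trip
    u <- c(0.05, 0.5, 0.95)
    expect_equal(prupture(qrupture(u, cs$p, cs$r), cs$p, cs$r), u, tolerance = 1e-10)
  }
})

test_that("the histogram mode of sampled rupture forces sits at the Evans-Ritchie force", {
  p <- bell_alone()
  f <- simulate_rupture_forces(p, 10, 1e4, seed = 4)
  mp <- most_probable_force(f, bin_width = 1)
  expect_lt(abs(mp$force - evans_ritchie_force(10, p)), 1)
})

test_that("rupture forces increase stochastically with loading rate", {
  p <- bell_alone()
  rates <- c(3, 10, 30, 100)
  draws <- lapply(seq_along(rates),
                  function(j) simulate_rupture_forces(p, rates[j], 2000, seed = 30 + j))
  expect_true(all(diff(vapply(draws, mean, numeric(1))) > 0))
  modes <- vapply(draws, function(f) most_probable_force(f, 1)$force, numeric(1))
  expect_true(all(diff(modes) > 0))
})

test_that("sampling is reproducible under a fixed seed and errors when k0 = 0", {
  p <- bell_alone()
  expect_identical(simulate_rupture_forces(p, 10, 50, seed = 9),
                   simulate_rupture_forces(p, 10, 50, seed = 9))
  expect_error(simulate_rupture_forces(bell_evans_params(0, 0.71), 10, 5, seed = 1),
               "k0 = 0")
})

test_that("a noiseless one-step trace carries exactly one rupture with the WLC jump", {
  pw <- one_step_pathway()
  proto <- pulling_protocol(loading_rate = 10, noise_sd_force = 0,
                            noise_sd_extension = 0, seed = 5)
  tr <- simulate_trace(pw, proto)
  expect_equal(nrow(tr$ground_truth), 1)
  expect_false(tr$truncated)
  ev <- detect_unfolding_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$rupture_force, tr$ground_truth$force, tolerance = 0.02)
  # detected gain equals the worm-like-chain jump of the released chain
  jump <- wlc_extension(ev$rupture_force, wlc_alone())
  expect_equal(ev$extension_gain, jump, tolerance = 0.01)
})

test_that("trace-level rupture forces agree in distribution with the analytic sampler", {
  pw <- one_step_pathway()
  gt <- replicate(500, NA_real_)
  set.seed(77)
  seeds <- sample.int(2^30, 500)
  for (i in 1:500) {
    proto <- pulling_protocol(loading_rate = 10, sampling_interval = 0.2,
                              max_force = 40, seed = seeds[i])
    tr <- simulate_trace(pw, proto)
    gt[i] <- if (nrow(tr$ground_truth) == 1) tr$ground_truth$force else NA
  }
  gt <- gt[!is.na(gt)]
  direct <- simulate_rupture_forces(bell_alone(), 10, 500, seed = 78)
  ks <- suppressWarnings(stats::ks.test(gt, direct))
  expect_gt(ks$p.value, 0.01)
})

test_that("a two-step pathway yields two ordered transitions that conserve length", {
  pw <- two_step_pathway()
  n2 <- 0; ordered <- TRUE
  for (i in 1:40) {
    proto <- pulling_protocol(loading_rate = 20, sampling_interval = 0.1,
                              noise_sd_force = 0, noise_sd_extension = 0,
                              seed = 400 + i)
    tr <- simulate_trace(pw, proto)
    if (nrow(tr$ground_truth) == 2) {
      n2 <- n2 + 1
      ordered <- ordered && diff(tr$ground_truth$time) > 0
      expect_equal(sum(tr$ground_truth$dLc), 55.3)
    }
  }
  expect_gt(n2, 20)  # the second step usually triggers before max force
  expect_true(ordered)
  # with slower second-step kinetics the second rupture is mostly at higher force
  proto <- pulling_protocol(loading_rate = 20, sampling_interval = 0.1, seed = 1)
  forces <- replicate(50, {
    tr <- simulate_trace(pw, pulling_protocol(20, sampling_interval = 0.1,
                                              seed = sample.int(2^30, 1)))
    if (nrow(tr$ground_truth) == 2) diff(tr$ground_truth$force) else NA
  })
  expect_gt(mean(forces > 0, na.rm = TRUE), 0.8)
})

test_that("traces are truncated, not failed, when transitions outlive the ramp", {
  pw <- unfolding_pathway(55.3, bell_evans_params(1e-6, 0.05), Lp = 0.28)
  proto <- pulling_protocol(loading_rate = 10, max_force = 15,
                            sampling_interval = 0.05, seed = 3)
  tr <- simulate_trace(pw, proto)
  expect_true(tr$truncated)
  expect_equal(nrow(tr$ground_truth), 0)
  expect_equal(nrow(detect_unfolding_events(tr)), 0)
})

test_that("simulate_experiment is seed-deterministic and honours per-rate counts", {
  pw <- one_step_pathway()
  a <- simulate_experiment(pw, loading_rates = c(5, 50), n_traces_per_rate = 3,
                           seed = 11, protocol_args = list(sampling_interval = 0.1))
  b <- simulate_experiment(pw, loading_rates = c(5, 50), n_traces_per_rate = 3,
                           seed = 11, protocol_args = list(sampling_interval = 0.1))
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$traces[[2]]$force, b$traces[[2]]$force)
  expect_equal(length(a$traces), 6)
  # zero traces for one rate is allowed
  z <- simulate_experiment(pw, loading_rates = c(5, 50), n_traces_per_rate = c(0, 2),
                           seed = 11, protocol_args = list(sampling_interval = 0.1))
  expect_equal(length(z$traces), 2)
  expect_true(all(z$loading_rate == 50))
  expect_error(simulate_experiment(pw, loading_rates = 5, n_traces_per_rate = 1),
               "seed")
})

test_that("pulling protocols validate their inputs and accept speed x stiffness", {
  expect_equal(pulling_protocol(pulling_speed = 100, effective_stiffness = 0.3)$loading_rate, 30)
  expect_error(pulling_protocol(loading_rate = -1), "> 0")
  expect_error(pulling_protocol(), "loading_rate")
  expect_error(unfolding_pathway(numeric(0), bell_alone()), "at least one")
  expect_error(unfolding_pathway(c(20, -5), bell_alone()), "> 0")
})
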