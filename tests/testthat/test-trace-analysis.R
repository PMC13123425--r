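test_that("a smooth ramp with no transition yields no events", {
  pw <- one_step_pathway()
  proto <- pulling_protocol(loading_rate = 10, max_force = 6,
                            sampling_interval = 0.02, seed = 8)
  tr <- simulate_trace(pw, proto)  # ruptures above 6 pN are cut off
  if (nrow(tr$ground_truth) == 0) {
    expect_equal(nrow(detect_unfolding_events(tr)), 0)
  }
  # deterministic no-event case: force-insensitive, glacially slow unfolder
  pw0 <- unfolding_pathway(55.3, bell_evans_params(1e-9, 0), Lp = 0.28)
  tr0 <- simulate_trace(pw0, pulling_protocol(10, sampling_interval = 0.02, seed = 8))
  expect_equal(nrow(detect_unfolding_events(tr0)), 0)
  expect_error(detect_unfolding_events(tr0, min_force_drop = 0), "> 0")
  expect_error(detect_unfolding_events(tr0, min_extension_gain = -1), "> 0")
})

test_that("a noiseless two-step trace yields two events", {
  pw <- two_step_pathway()
  found <- FALSE
  for (s in 1:10) {
    tr <- simulate_trace(pw, pulling_protocol(20, noise_sd_force = 0,
                                              noise_sd_extension = 0, seed = 600 + s))
    if (nrow(tr$ground_truth) == 2 && all(tr$ground_truth$force > 9)) {
      ev <- detect_unfolding_events(tr)
      expect_equal(nrow(ev), 2)
      expect_equal(ev$rupture_force, tr$ground_truth$force, tolerance = 0.03)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("detection has full recall and precision for in-band events at low noise", {
  pw <- one_step_pathway()
  hits <- 0; gt_in_band <- 0; false_pos <- 0
  for (i in 1:40) {
    proto <- pulling_protocol(loading_rate = 20, seed = 900 + i,
                              noise_sd_force = 0.25, noise_sd_extension = 1)
    tr <- simulate_trace(pw, proto)
    ev <- suppressWarnings(detect_unfolding_events(tr))
    truth <- tr$ground_truth
    in_band <- truth$force[truth$force >= 10 & truth$force <= 25]
    gt_in_band <- gt_in_band + length(in_band)
    for (f0 in in_band) {
      if (any(abs(ev$rupture_force - f0) < 1)) hits <- hits + 1
    }
    false_pos <- false_pos +
      sum(!vapply(ev$rupture_force,
                  function(f) any(abs(truth$force - f) < 1), logical(1)))
  }
  expect_gt(gt_in_band, 20)
  expect_equal(hits, gt_in_band)   # recall 1.0
  expect_equal(false_pos, 0)       # precision 1.0
})

test_that("event count never exceeds the number of pathway transitions at low noise", {
  pw <- two_step_pathway()
  for (i in 1:25) {
    tr <- simulate_trace(pw, pulling_protocol(20, seed = 1200 + i,
                                              noise_sd_force = 0.2,
                                              noise_sd_extension = 1))
    ev <- suppressWarnings(detect_unfolding_events(tr))
    expect_lte(nrow(ev), 2)
  }
})

test_that("most_probable_force returns the tallest bin centre with half-bin error", {
  mp <- most_probable_force(rep(12.0, 20), bin_width = 1)
  expect_equal(mp$force, 12.5)
  expect_equal(mp$half_bin, 0.5)
  # tie broken toward the lower-force bin
  tie <- most_probable_force(c(1.2, 1.4, 3.3, 3.6), bin_width = 1)
  expect_equal(tie$force, 1.5)
  expect_error(most_probable_force(numeric(0)), "at least one")
  expect_error(most_probable_force(10, bin_width = 0), "> 0")
})

test_that("most_probable_force is invariant to ordering and small origin shifts", {
  f <- simulate_rupture_forces(bell_alone(), 10, 2000, seed = 2)
  mp <- most_probable_force(f, 1)
  expect_equal(most_probable_force(rev(f), 1)$force, mp$force)
  expect_equal(most_probable_force(sample(f), 1)$force, mp$force)
  shifted <- most_probable_force(f, 1, origin = 0.05)
  expect_lte(abs(shifted$force - mp$force), 1)
})

test_that("summarize_extensions reports the Gaussian mean and HWHM", {
  set.seed(6)
  g <- rnorm(500, mean = 40, sd = 4)
  s <- summarize_extensions(g)
  expect_equal(s$gaussian_mean, 40, tolerance = 0.02)
  expect_equal(s$hwhm, 4 * sqrt(2 * log(2)), tolerance = 0.1)
  expect_equal(4 * sqrt(2 * log(2)), 4.71, tolerance = 1e-3)
  expect_equal(s$n_events, 500)
  expect_error(summarize_extensions(c(10, 10, 10)), "degenerate")
  expect_error(summarize_extensions(c(10, 12)), "at least 3")
})

test_that("one-step unfolding extensions fall in the long-extension band at high force", {
  # when the rupture force is high enough that the fractional extension
  # exceeds ~0.54, a 55.3 nm step releases a 30-50 nm jump
  pw <- one_step_pathway()
  gains <- c(); forces <- c()
  for (i in 1:80) {
    tr <- simulate_trace(pw, pulling_protocol(100, seed = 2200 + i,
                                              max_force = 40))
    ev <- suppressWarnings(detect_unfolding_events(tr))
    ok <- !is.na(ev$extension_gain)
    gains <- c(gains, ev$extension_gain[ok])
    forces <- c(forces, ev$rupture_force[ok])
  }
  sel <- wlc_extension(forces, wlc_alone()) / 55.3 > 0.54 & forces < 35
  expect_gt(sum(sel), 10)
  s <- summarize_extensions(gains[sel])
  expect_gt(s$gaussian_mean, 30)
  expect_lt(s$gaussian_mean, 50)
  # inside the 8-20 pN rupture band the same step reads 20-30 nm
  band <- forces >= 8 & forces <= 20
  if (sum(band) >= 3) {
    expect_gt(mean(gains[band]), 18)
    expect_lt(mean(gains[band]), 32)
  }
})

test_that("estimate_loading_rate recovers the ramp slope", {
  pw <- one_step_pathway()
  tr <- simulate_trace(pw, pulling_protocol(10, noise_sd_force = 0,
                                            noise_sd_extension = 0, seed = 31))
  n_pre <- max(which(tr$time < tr$ground_truth$time))
  expect_equal(estimate_loading_rate(tr, n_pre), 10, tolerance = 1e-6)
  # noisy ramp with a comfortably late rupture: within 5 percent
  for (s in 32:60) {
    trn <- simulate_trace(pw, pulling_protocol(10, seed = s))
    if (nrow(trn$ground_truth) == 1 && trn$ground_truth$force > 8) break
  }
  n_pre <- max(which(trn$time < trn$ground_truth$time))
  expect_equal(estimate_loading_rate(trn, n_pre), 10, tolerance = 0.05)
  # too-short window falls back to the nominal rate with a warning
  expect_warning(r <- estimate_loading_rate(tr, 4), "nominal")
  expect_equal(r, 10)
})
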