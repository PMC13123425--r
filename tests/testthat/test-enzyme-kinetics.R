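test_that("initial_rate is exact on linear and constant progress curves", {
  t <- seq(0, 3600, by = 120)
  expect_equal(initial_rate(data.frame(time = t, rfu = 100 + 5 * t)), 5,
               tolerance = 1e-12)
  expect_equal(initial_rate(data.frame(time = t, rfu = rep(250, length(t)))), 0,
               tolerance = 1e-12)
  expect_error(initial_rate(data.frame(time = t, rfu = 5 * t), window = 150),
               "at least 3")
})

test_that("initial_rate recovers the early slope of a saturating curve", {
  plateau <- 2000; k <- 2e-4  # early slope 0.4 RFU/s
  tr <- simulate_progress_curve(plateau, k, noise_sd = 0.01 * plateau * k * 600,
                                seed = 3)
  v <- initial_rate(tr)
  # the exponential itself bends the 10-minute window by a few percent
  expect_equal(v, plateau * k, tolerance = 0.07)
  tr0 <- simulate_progress_curve(plateau, k, noise_sd = 0)
  expect_equal(initial_rate(tr0, window = 240), plateau * k, tolerance = 0.03)
})

test_that("relative_activity calibrates rates against the standard curve", {
  sc <- standard_curve(c(0, 6.25, 12.5, 25), c(0, 6.25, 12.5, 25) * 0.04,
                       reference_conc = 12.5)
  ref_rate <- 12.5 * 0.04
  expect_equal(relative_activity(ref_rate, sc), 100)
  expect_equal(relative_activity(ref_rate / 2, sc), 50)
  expect_warning(z <- relative_activity(-0.01, sc), "clamped")
  expect_equal(z, 0)
  expect_error(standard_curve(c(0, 12.5), c(1, 0)), "slope")
  expect_error(standard_curve(12.5, 1), "at least 2")
})

test_that("relative_activity is invariant to the fluorescence unit scale", {
  sc1 <- standard_curve(c(0, 12.5, 25), c(0, 0.5, 1.0))
  sc2 <- standard_curve(c(0, 12.5, 25), 1000 * c(0, 0.5, 1.0))
  expect_equal(relative_activity(0.3, sc1), relative_activity(300, sc2))
})

test_that("a simulated assay at the reference enzyme concentration reads 100 percent", {
  # progress curves at known enzyme concentrations define the standard curve;
  # the working concentration (12.5 nM) must then read back as ~100 percent
  rate_per_nM <- 0.032
  calib_conc <- c(6.25, 25)
  calib_rate <- vapply(calib_conc, function(cc) {
    initial_rate(simulate_progress_curve(plateau = 3000,
                                         rate_constant = cc * rate_per_nM / 3000,
                                         noise_sd = 1, seed = 50 + cc))
  }, numeric(1))
  sc <- standard_curve(calib_conc, calib_rate, reference_conc = 12.5)
  v <- initial_rate(simulate_progress_curve(plateau = 3000,
                                            rate_constant = 12.5 * rate_per_nM / 3000,
                                            noise_sd = 1, seed = 99))
  expect_equal(relative_activity(v, sc), 100, tolerance = 0.05)
})

test_that("enhancement_profile summarises fold change over ligand concentration", {
  flat <- data.frame(conc = c(0, 125, 250, 500), activity = c(100, 101, 99, 100))
  expect_equal(enhancement_profile(flat)$max_fold, 1.01, tolerance = 1e-12)
  doubling <- data.frame(conc = c(0, 125, 250, 500), activity = c(100, 130, 170, 200))
  ep <- enhancement_profile(doubling)
  expect_equal(ep$max_fold, 2.0)
  expect_equal(ep$at_conc, 500)
  expect_error(enhancement_profile(data.frame(conc = c(125, 500),
                                              activity = c(100, 200))),
               "zero-concentration")
})

test_that("a saturating mutant-like profile reports a two-fold maximum", {
  # activities simulated from progress curves whose rate doubles with ligand
  set.seed(123)
  conc <- c(0, 31.25, 62.5, 125, 250, 500)
  fold_true <- 1 + conc / (conc + 60)  # saturates near 2
  sc <- standard_curve(c(0, 12.5, 25), c(0, 0.4, 0.8), reference_conc = 12.5)
  act <- vapply(seq_along(conc), function(i) {
    v <- 0.4 * fold_true[i] * (1 + rnorm(1, 0, 0.02))
    relative_activity(v, sc)
  }, numeric(1))
  ep <- enhancement_profile(data.frame(conc = conc, activity = act))
  expect_equal(ep$max_fold, max(fold_true), tolerance = 0.1)
  expect_gte(ep$max_fold, 1)
})
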