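test_that("bell_rate reproduces the exponential force dependence", {
  p <- bell_alone()
  expect_equal(bell_rate(0, p), 0.15)
  # at F = kBT/gamma the rate is k0 * e
  expect_equal(bell_rate(p$kBT / p$gamma, p), 0.15 * exp(1), tolerance = 1e-12)
  # gamma = 0: force-insensitive
  p0 <- bell_evans_params(0.2, 0)
  expect_equal(bell_rate(c(0, 5, 50), p0), rep(0.2, 3))
  expect_error(bell_rate(-1, p), "force")
})

test_that("evans_ritchie_force matches the closed form and its slope property", {
  p <- bell_alone()
  f10 <- (p$kBT / p$gamma) * log(p$gamma * 10 / (p$k0 * p$kBT))
  expect_equal(evans_ritchie_force(10, p), f10, tolerance = 1e-12)
  expect_equal(f10, 14.15, tolerance = 1e-3)
  expect_gt(f10, 8); expect_lt(f10, 20)  # inside the observed rupture band
  # doubling the rate adds kBT*ln(2)/gamma
  expect_equal(evans_ritchie_force(20, p) - evans_ritchie_force(10, p),
               p$kBT * log(2) / p$gamma, tolerance = 1e-9)
  expect_equal(p$kBT * log(2) / p$gamma, 4.01, tolerance = 1e-2)
  # affine in log(rate)
  r <- c(2, 8, 32)
  f <- evans_ritchie_force(r, p)
  expect_equal(diff(f)[1], diff(f)[2], tolerance = 1e-9)
})

test_that("evans_ritchie_force clamps unphysical negative modes to zero", {
  p <- bell_alone()
  r0 <- p$k0 * p$kBT / p$gamma
  expect_warning(f <- evans_ritchie_force(r0, p), "clamped")
  expect_equal(f, 0)
  expect_warning(expect_equal(evans_ritchie_force(r0 / 2, p), 0))
  expect_error(evans_ritchie_force(10, bell_evans_params(0.15, 0)), "gamma > 0")
  expect_error(evans_ritchie_force(10, bell_evans_params(0, 0.71)), "k0 > 0")
  expect_error(evans_ritchie_force(0, p), "> 0")
})

test_that("fit_bell_evans recovers generating parameters exactly on clean data", {
  for (truth in list(bell_alone(), bell_wt(), bell_mut())) {
    r <- c(1, 3, 10, 30, 100)
    pts <- data.frame(loading_rate = r,
                      force = suppressWarnings(evans_ritchie_force(r, truth)))
    pts <- pts[pts$force > 0, ]
    fit <- fit_bell_evans(pts)
    expect_equal(fit$params$k0, truth$k0, tolerance = 1e-6)
    expect_equal(fit$params$gamma, truth$gamma, tolerance = 1e-6)
    # linear back-transform route agrees with the nonlinear route
    lin <- fit_bell_evans(pts, method = "linear")
    expect_equal(lin$params$k0, fit$params$k0, tolerance = 1e-6)
    expect_equal(lin$params$gamma, fit$params$gamma, tolerance = 1e-6)
  }
})

test_that("fit_bell_evans solves two exact points and rejects degenerate input", {
  truth <- bell_alone()
  r <- c(5, 50)
  pts <- data.frame(loading_rate = r, force = evans_ritchie_force(r, truth))
  fit <- fit_bell_evans(pts)
  expect_equal(fit$params$k0, truth$k0, tolerance = 1e-9)
  expect_equal(fit$params$gamma, truth$gamma, tolerance = 1e-9)
  expect_error(fit_bell_evans(data.frame(loading_rate = c(10, 10), force = c(12, 14))),
               "distinct loading rates")
})

test_that("crossover_force equates the two rate curves and is symmetric", {
  a <- bell_alone(); b <- bell_wt(); m <- bell_mut()
  fx <- crossover_force(a, b)
  expect_equal(fx, 7.66, tolerance = 1e-3)
  expect_equal(round(fx), 8)  # "approximately 8 pN"
  expect_equal(crossover_force(a, m), 9.11, tolerance = 1e-3)
  expect_equal(bell_rate(fx, a), bell_rate(fx, b), tolerance = 1e-12)
  expect_equal(crossover_force(b, a), fx, tolerance = 1e-12)
  expect_error(crossover_force(a, a), "degenerate|parallel")
  expect_error(crossover_force(a, bell_evans_params(0.3, 0.71)), "degenerate|parallel")
  expect_error(crossover_force(a, bell_evans_params(0.017, 1.88, kBT = 4.0)), "kBT")
})

test_that("stability_profile is below 1 under the crossover and above it beyond", {
  a <- bell_alone(); b <- bell_wt()
  prof <- stability_profile(c(0, 15), a, b)
  expect_equal(prof$rate_ratio[1], 0.017 / 0.15, tolerance = 1e-12)
  expect_lt(prof$rate_ratio[1], 1)   # stabilized at zero force
  expect_gt(prof$rate_ratio[2], 1)   # destabilized at 15 pN
  fx <- crossover_force(a, b)
  expect_equal(stability_profile(fx, a, b)$rate_ratio, 1, tolerance = 1e-12)
  expect_error(stability_profile(numeric(0), a, b), "non-empty")
})
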