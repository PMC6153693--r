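test_that("exact power laws are recovered to numerical precision", {
  q <- q_log_grid(1e-2, 1e1, 200)
  curve <- scattering_curve(q, q^-2.28)
  fit <- fit_power_law(curve, regime_bounds(min(q), max(q), length(q)))
  expect_equal(fit$slope, -2.28, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$slope_stderr, 1e-10)
})

test_that("a constant curve fits slope zero with r^2 treated as perfect", {
  q <- q_log_grid(0.1, 10, 20)
  fit <- fit_power_law(scattering_curve(q, rep(3.7, 20)),
                       regime_bounds(0.1, 10, 20))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("three-point fit matches hand-computed OLS values", {
  # log10 q = {0, 1, 2}, log10 I = {0, -2, -4.3}:
  # slope = -2.15, intercept = 0.05, RSS = 0.015,
  # stderr = sqrt(0.015 / 1 / 2) = 0.0866025, r^2 = 1 - 0.015/9.26
  curve <- scattering_curve(c(1, 10, 100), 10^c(0, -2, -4.3))
  fit <- fit_power_law(curve, regime_bounds(1, 100, 3))
  expect_equal(fit$slope, -2.15, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-12)
  expect_equal(fit$slope_stderr, sqrt(0.0075), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1 - 0.015 / 9.26, tolerance = 1e-12)
  # and agrees with the independent closed-form oracle
  o <- ols_oracle(c(0, 1, 2), c(0, -2, -4.3))
  expect_equal(fit$slope, o$slope)
  expect_equal(fit$slope_stderr, o$stderr)
})

test_that("fits require at least three points and positive intensities", {
  q <- q_log_grid(0.1, 10, 20)
  curve <- scattering_curve(q, q^-2)
  expect_error(fit_power_law(curve, regime_bounds(0.1, 0.12, 3)),
               "insufficient")
})

test_that("Student-t interval uses n-2 degrees of freedom", {
  q <- q_log_grid(1, 100, 4)
  fit <- fit_power_law(scattering_curve(q, q^-2), regime_bounds(1, 100, 4))
  fit$slope_stderr <- 0.01   # hand-set residual scale, n = 4
  expect_equal(student_t_ci(fit, 0.95), 0.01 * 4.30265272974946,
               tolerance = 1e-10)
  # perfect fit -> zero halfwidth
  fit0 <- fit_power_law(scattering_curve(q, q^-2), regime_bounds(1, 100, 4))
  expect_equal(student_t_ci(fit0), 0, tolerance = 1e-10)
  # halfwidth strictly increasing in the confidence level
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  hw <- vapply(levels, function(l) student_t_ci(fit, l), numeric(1))
  expect_true(all(diff(hw) > 0))
  expect_error(student_t_ci(fit, 1.2), "\\(0, 1\\)")
})

test_that("an exact power law over the whole grid detects the full grid", {
  q <- q_log_grid(0.05, 5, 60)
  bounds <- detect_power_law_regime(scattering_curve(q, 3 * q^-2.1))
  expect_equal(bounds$q_low, min(q))
  expect_equal(bounds$q_high, max(q))
  expect_equal(bounds$n_points, 60L)
})

test_that("detection recovers composite crossovers within one grid step", {
  m <- floc_model(a = 20, Rp = 0.5)   # crossovers at 0.05 and 2 per um
  grid <- default_test_grid()
  step <- (max(grid) / min(grid))^(1 / (length(grid) - 1))
  bounds <- detect_power_law_regime(composite_intensity(m, grid))
  expect_gt(bounds$q_low, 0.05 / step)
  expect_lt(bounds$q_low, 0.05 * step)
  expect_gt(bounds$q_high, 2 / step)
  expect_lt(bounds$q_high, 2 * step)
})

test_that("curves without a fractal regime raise a no-regime error", {
  # pure Guinier curvature: q*Rg < 1 everywhere
  q <- q_log_grid(1e-4, 9e-3, 80)
  guinier <- scattering_curve(q, exp(-(q * 100)^2 / 3))
  expect_error(detect_power_law_regime(guinier),
               class = "flocscatter_no_regime")
  # flat noise: high scatter defeats the r^2 gate
  noisy <- scattering_curve(q_log_grid(0.1, 10, 80),
                            exp(sin((1:80) * 2.7)))
  expect_error(detect_power_law_regime(noisy),
               class = "flocscatter_no_regime")
})

test_that("detection skips the Porod branch in favour of the fractal regime", {
  # Porod window is the longest pure power law on this grid, but its
  # slope magnitude 4 exceeds any mass-fractal dimension
  m <- floc_model(Df = 2.2, Rp = 0.7, a = 25)
  bounds <- detect_power_law_regime(composite_intensity(m, default_test_grid()))
  fit <- fit_power_law(composite_intensity(m, default_test_grid()), bounds)
  expect_equal(-fit$slope, 2.2, tolerance = 1e-6)
})

test_that("detection is idempotent on its own bounds", {
  curves <- list(
    composite_intensity(floc_model(Df = 2.1), default_test_grid()),
    composite_intensity(floc_model(Df = 2.9, a = 30, Rp = 0.8),
                        default_test_grid()),
    generate_scattering_sample(Df = 2.2, seed = 11)$curve
  )
  for (curve in curves) {
    b1 <- detect_power_law_regime(curve)
    sel <- curve$q >= b1$q_low & curve$q <= b1$q_high
    b2 <- detect_power_law_regime(
      scattering_curve(curve$q[sel], curve$intensity[sel]))
    expect_equal(b2$q_low, b1$q_low)
    expect_equal(b2$q_high, b1$q_high)
  }
})

test_that("q-diameter conversion is reciprocal and round-trips", {
  expect_equal(q_to_diameter(0.1), 10)
  d <- c(0.3, 1, 30, 245)
  expect_equal(q_to_diameter(1 / d), d)
  expect_equal(q_to_diameter(1 / 30), 30)
  expect_equal(q_to_diameter(1, "two_pi"), 2 * pi)
  expect_error(q_to_diameter(0), "positive")
  # regime bounds map to the reciprocal diameter pair
  expect_equal(q_to_diameter(c(1 / 30, 1 / 0.8)), c(30, 0.8))
})

test_that("RGD validity is a strict comparison against the wavelength", {
  optics <- optical_config()
  expect_true(rgd_validity_flag(0.1, optics))
  expect_false(rgd_validity_flag(30, optics))
  expect_false(rgd_validity_flag(optics$wavelength_um, optics))
})

test_that("the pipeline recovers a noiseless generating dimension", {
  s <- generate_scattering_sample(Df = 2.26, rel_noise_sd = 0, seed = 1)
  res <- fd_pipeline(s$curve)
  expect_equal(res$fd, 2.26, tolerance = 1e-3)
  expect_equal(res$d_min_um, 1 / res$bounds$q_high)
  expect_equal(res$d_max_um, 1 / res$bounds$q_low)
  expect_true(res$exceeds_rgd)   # floc regimes reach tens of micrometres
  expect_equal(res$rgd_valid_up_to_um, 0.6328)
})

test_that("fd and interval are invariant to overall intensity scale", {
  s <- generate_scattering_sample(Df = 2.15, seed = 3)
  r1 <- fd_pipeline(s$curve)
  scaled <- scattering_curve(s$curve$q, 137.5 * s$curve$intensity)
  r2 <- fd_pipeline(scaled)
  expect_equal(r2$fd, r1$fd, tolerance = 1e-12)
  expect_equal(r2$ci_halfwidth, r1$ci_halfwidth, tolerance = 1e-12)
  expect_equal(r2$bounds$q_low, r1$bounds$q_low)
  expect_equal(r2$bounds$q_high, r1$bounds$q_high)
})

test_that("a slope outside the physical range warns but is reported", {
  q <- q_log_grid(0.1, 10, 50)
  steep <- scattering_curve(q, q^-0.5)
  expect_warning(res <- fd_pipeline(steep), "outside")
  expect_equal(res$fd, 0.5, tolerance = 1e-10)
})

test_that("interval halfwidth shrinks as one over root n", {
  # same q-range and noise level, 8x the grid points
  mean_ci <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      q <- q_log_grid(0.1, 10, n)
      clean <- scattering_curve(q, q^-2.2)
      noisy <- simulate_measurement(clean, rel_noise_sd = 0.02,
                                    n_reps = 1, seed = s)
      student_t_ci(fit_power_law(noisy, regime_bounds(0.1, 10, n)))
    }, numeric(1)))
  }
  seeds <- 1:40
  ratio <- mean_ci(25, seeds) / mean_ci(200, seeds)
  expect_gt(ratio, sqrt(8) * 0.8)
  expect_lt(ratio, sqrt(8) * 1.2)
})

test_that("generating dimensions across the observed span are recovered", {
  # median absolute error < 0.02 and max < 0.05 over 50 seeds per value
  for (df in c(1.98, 2.07, 2.20, 2.34)) {
    err <- vapply(1:50, function(i) {
      s <- generate_scattering_sample(Df = df, seed = 5000 + i)
      abs(fd_pipeline(s$curve)$fd - df)
    }, numeric(1))
    expect_lt(median(err), 0.02)
    expect_lt(max(err), 0.05)
  }
})
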