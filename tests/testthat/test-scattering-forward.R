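test_that("scattering-vector conversion follows the standard definition", {
  optics <- optical_config(wavelength_um = 0.6328,
                           medium_refractive_index = 1)
  expect_identical(q_from_angle(0, optics), 0)
  # backscattering limit: q = 4*pi*n/lambda
  expect_equal(q_from_angle(180, optics), 4 * pi / 0.6328, tolerance = 1e-12)
  # strictly increasing in angle
  theta <- seq(0, 180, by = 5)
  expect_true(all(diff(q_from_angle(theta, optical_config())) > 0))
  expect_error(q_from_angle(-1), "\\[0, 180\\]")
  expect_error(q_from_angle(181), "\\[0, 180\\]")
})

test_that("Guinier quadratic law has the right limits and domain", {
  expect_equal(guinier_intensity(0, Rg = 100, I0 = 3), 3)
  expect_equal(guinier_intensity(1 / 100, Rg = 100, I0 = 1), 2 / 3)
  # agrees with the exponential Guinier law to 0.5% for q*Rg <= 0.3
  q <- seq(1e-4, 0.3, length.out = 50)
  rel <- abs(guinier_intensity(q, Rg = 1) / exp(-q^2 / 3) - 1)
  expect_lt(max(rel), 0.005)
  expect_error(guinier_intensity(sqrt(3) / 50, Rg = 50), "invalid")
})

test_that("fractal and Porod laws are exact power laws", {
  expect_equal(fractal_intensity(10, Df = 2), 0.01)
  expect_equal(fractal_intensity(1, Df = 2.7, C = 5), 5)
  expect_equal(porod_intensity(2), 1 / 16)
  q <- q_log_grid(0.01, 10, 40)
  expect_equal(porod_intensity(q, C = 3), fractal_intensity(q, Df = 4, C = 3))
  # OLS log-log slope recovers the generating exponent to machine precision
  fit <- ols_oracle(log10(q), log10(fractal_intensity(q, Df = 2.34, C = 7)))
  expect_equal(fit$slope, -2.34, tolerance = 1e-12)
  expect_error(fractal_intensity(0, Df = 2), "positive")
  expect_error(fractal_intensity(1, Df = 2, C = -1), "positive")
})

test_that("RGD sphere form factor matches its closed-form properties", {
  expect_equal(rgd_sphere_form_factor(0, R = 1), 1)
  x <- seq(0.01, 30, length.out = 2000)
  p <- rgd_sphere_form_factor(x, R = 1)
  expect_true(all(p >= 0 & p <= 1))
  # first zero at the first positive root of tan x = x, found independently
  root <- uniroot(function(x) sin(x) - x * cos(x), c(pi, 1.5 * pi),
                  tol = 1e-12)$root
  expect_equal(root, 4.493409, tolerance = 1e-6)
  expect_lt(rgd_sphere_form_factor(root, R = 1), 1e-12)
  # series and direct branches agree near the switch point
  x0 <- 0.09
  direct <- (3 * (sin(x0) - x0 * cos(x0)) / x0^3)^2
  expect_equal(rgd_sphere_form_factor(x0, R = 1), direct, tolerance = 1e-9)
  expect_error(rgd_sphere_form_factor(1, R = 0), "positive")
})

test_that("form-factor maxima envelope decays with the Porod exponent", {
  x <- seq(50, 500, length.out = 200001)
  p <- rgd_sphere_form_factor(x, R = 1)
  interior <- 2:(length(x) - 1)
  imax <- interior[p[interior] > p[interior - 1] & p[interior] > p[interior + 1]]
  expect_gt(length(imax), 100)
  fit <- ols_oracle(log10(x[imax]), log10(p[imax]))
  expect_equal(fit$slope, -4, tolerance = 0.01)
})

test_that("small-angle form factor reproduces the Guinier 1/3 coefficient", {
  # (1 - P)/x^2 -> 1/5 as x -> 0
  x <- c(1e-3, 5e-3, 1e-2)
  coef5 <- (1 - rgd_sphere_form_factor(x, R = 1)) / x^2
  expect_equal(coef5, rep(1 / 5, 3), tolerance = 1e-4)
  # with Rg^2 = (3/5) R^2 for a sphere this is the 1/3 Guinier coefficient
  R <- 2
  Rg <- sqrt(3 / 5) * R
  q <- c(1e-3, 2e-3, 5e-3)
  coef3 <- (1 - rgd_sphere_form_factor(q, R = R)) / (q * Rg)^2
  expect_equal(coef3, rep(1 / 3, 3), tolerance = 1e-4)
})

test_that("composite curve is continuous, positive and non-increasing", {
  m <- floc_model()
  q1 <- 1 / m$a
  q2 <- 1 / m$Rp
  eps <- 1e-9
  grid <- sort(c(q_log_grid(1e-3, 1e2, 150),
                 q1 * (1 - eps), q1, q1 * (1 + eps),
                 q2 * (1 - eps), q2, q2 * (1 + eps)))
  curve <- composite_intensity(m, grid)
  expect_true(all(curve$intensity > 0))
  expect_true(all(diff(curve$intensity) <= 0))
  at <- function(q) curve$intensity[which.min(abs(curve$q - q))]
  i_lo <- curve$intensity[curve$q >= q1 * (1 - 2 * eps) & curve$q <= q1 * (1 + 2 * eps)]
  expect_lt(diff(range(i_lo)) / mean(i_lo), 1e-6)
  i_hi <- curve$intensity[curve$q >= q2 * (1 - 2 * eps) & curve$q <= q2 * (1 + 2 * eps)]
  expect_lt(diff(range(i_hi)) / mean(i_hi), 1e-6)
})

test_that("composite branches carry exactly their generating exponents", {
  m <- floc_model(Df = 2.26)
  curve <- composite_intensity(m, default_test_grid())
  # interior of the fractal regime
  sel <- curve$q >= 2 / m$a & curve$q <= 1 / (2 * m$Rp)
  fit <- ols_oracle(log10(curve$q[sel]), log10(curve$intensity[sel]))
  expect_equal(fit$slope, -2.26, tolerance = 1e-6)
  # Porod branch
  sel <- curve$q > 2 / m$Rp
  fit <- ols_oracle(log10(curve$q[sel]), log10(curve$intensity[sel]))
  expect_equal(fit$slope, -4, tolerance = 1e-6)
})

test_that("composite rejects grids missing a crossover", {
  m <- floc_model()   # 1/a = 0.05, 1/Rp = 2
  expect_error(composite_intensity(m, q_log_grid(0.1, 100, 50)), "1/a")
  expect_error(composite_intensity(m, q_log_grid(1e-3, 1, 50)), "1/Rp")
})

test_that("measurement simulation is seeded, unbiased and noise-free at sd 0", {
  curve <- composite_intensity(floc_model(), default_test_grid(60))
  expect_identical(simulate_measurement(curve, rel_noise_sd = 0, seed = 5),
                   curve)
  a <- simulate_measurement(curve, rel_noise_sd = 0.05, seed = 42)
  b <- simulate_measurement(curve, rel_noise_sd = 0.05, seed = 42)
  expect_identical(a, b)
  c <- simulate_measurement(curve, rel_noise_sd = 0.05, seed = 43)
  expect_false(identical(a$intensity, c$intensity))
  # lognormal mean identity: average of many replicates -> exp(sd^2/2) * input
  small <- scattering_curve(c(0.1, 1, 10), c(100, 1, 0.01))
  avg <- simulate_measurement(small, rel_noise_sd = 0.05, n_reps = 1e4,
                              seed = 7)
  expect_equal(avg$intensity / small$intensity,
               rep(exp(0.05^2 / 2), 3), tolerance = 0.01)
  expect_error(simulate_measurement(curve, rel_noise_sd = -0.1),
               "non-negative")
})

test_that("measurement simulation leaves the caller's RNG state alone", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_measurement(
    composite_intensity(floc_model(), default_test_grid(30)),
    rel_noise_sd = 0.05, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("aggregate model validates its parameter constraints", {
  expect_error(aggregate_model(Rg = 100, Rp = 25, a = 20, Df = 2.2), "Rp")
  expect_error(aggregate_model(Rg = 0.4, Rp = 0.5, a = 20, Df = 2.2), "Rp")
  expect_error(aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 1.0),
               "\\(1, 3\\]")
  expect_error(aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 3.2),
               "\\(1, 3\\]")
  expect_error(scattering_curve(c(1, 2), c(1, 0)), "positive")
  expect_error(scattering_curve(c(2, 1), c(1, 1)), "increasing")
})
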