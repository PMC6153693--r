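#' Scattering curve container
#'
#' Pairs a strictly increasing, strictly positive grid of
#' scattering-vector magnitudes with the relative scattered intensity
#' measured (or simulated) at each grid point. Intensity is a power, so
#' zeros and negative values are rejected.
#'
#' @param q Scattering-vector magnitudes in inverse micrometres;
#'   strictly increasing, all positive, at least two points.
#' @param intensity Relative intensities, same length as `q`, all
#'   strictly positive.
#'
#' @return An object of class `scattering_curve`: a list with numeric
#'   vectors `q` and `intensity`.
#' @examples
#' scattering_curve(q = c(0.1, 1, 10), intensity = c(100, 1, 0.01))
#' @export
scattering_curve <- function(q, intensity) {
  if (!is.numeric(q) || length(q) < 2L || any(!is.finite(q))) {
    stop("`q` must be finite numeric of length >= 2", call. = FALSE)
  }
  if (any(q <= 0)) stop("all `q` values must be positive", call. = FALSE)
  if (any(diff(q) <= 0)) {
    stop("`q` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(intensity) || length(intensity) != length(q) ||
      any(!is.finite(intensity))) {
    stop("`intensity` must be finite numeric, same length as `q`",
         call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("intensities must be strictly positive (intensity is a power)",
         call. = FALSE)
  }
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("Scattering curve: %d points, q in [%.4g, %.4g] 1/um\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Fractal aggregate model parameters
#'
#' Ground-truth generative parameters for a population of fractal
#' aggregates: the radius of gyration `Rg` of the whole floc, the
#' primary-particle size `Rp`, the size `a` of the largest structure
#' that scatters below the Porod (surface-scattering) regime, the mass
#' fractal dimension `Df`, and an overall intensity prefactor. The
#' reciprocals `1/a` and `1/Rp` bound the power-law (fractal) regime in
#' scattering-vector space.
#'
#' @param Rg Radius of gyration, micrometres (> 0, > `Rp`).
#' @param Rp Primary-particle size, micrometres (> 0).
#' @param a Largest non-Porod structure size, micrometres (> `Rp`).
#' @param Df Fractal dimension, dimensionless in `(1, 3]`.
#' @param I0 Intensity prefactor at zero angle (> 0). Default 1.
#'
#' @return An object of class `aggregate_model`.
#' @examples
#' aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 2.26)
#' @export
aggregate_model <- function(Rg, Rp, a, Df, I0 = 1) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(Rg) || Rg <= 0) stop("`Rg` must be a positive length (um)", call. = FALSE)
  if (!num1(Rp) || Rp <= 0) stop("`Rp` must be a positive length (um)", call. = FALSE)
  if (!num1(a) || a <= 0) stop("`a` must be a positive length (um)", call. = FALSE)
  if (!num1(I0) || I0 <= 0) stop("`I0` must be positive", call. = FALSE)
  if (!num1(Df) || Df <= 1 || Df > 3) {
    stop("`Df` must lie in (1, 3]", call. = FALSE)
  }
  if (Rp >= a) stop("`Rp` must be smaller than `a`", call. = FALSE)
  if (Rp >= Rg) stop("`Rp` must be smaller than `Rg`", call. = FALSE)
  structure(list(Rg = Rg, Rp = Rp, a = a, Df = Df, I0 = I0),
            class = "aggregate_model")
}

#' @export
print.aggregate_model <- function(x, ...) {
  cat("Fractal aggregate model\n")
  cat(sprintf("  Rg = %g um, Rp = %g um, a = %g um, Df = %g, I0 = %g\n",
              x$Rg, x$Rp, x$a, x$Df, x$I0))
  cat(sprintf("  power-law regime: q in [%.4g, %.4g] 1/um\n",
              1 / x$a, 1 / x$Rp))
  invisible(x)
}

#' Guinier small-angle intensity
#'
#' Quadratic (truncated) Guinier law
#' \eqn{I(q) = I_0 (1 - (q R_g)^2 / 3)}, valid at small `q * Rg` where
#' the scattered intensity depends only on the radius of gyration. The
#' truncation turns negative at \eqn{qR_g \ge \sqrt 3}, so such inputs
#' are rejected; see [composite_intensity()] for the exponential form
#' used across a full curve.
#'
#' @param q Scattering vector(s), 1/um, non-negative.
#' @param Rg Radius of gyration, micrometres (> 0).
#' @param I0 Zero-angle intensity (> 0). Default 1.
#'
#' @return Intensity values; `I0` at `q = 0`, decreasing in `q`.
#' @examples
#' guinier_intensity(c(0, 0.005, 0.01), Rg = 100)
#' @export
guinier_intensity <- function(q, Rg, I0 = 1) {
  stopifnot(is.numeric(q), is.numeric(Rg), length(Rg) == 1L, Rg > 0,
            is.numeric(I0), length(I0) == 1L, I0 > 0)
  if (any(q < 0)) stop("`q` must be non-negative", call. = FALSE)
  if (any(q * Rg >= sqrt(3))) {
    stop("Guinier expansion invalid: q*Rg >= sqrt(3) gives non-positive ",
         "intensity", call. = FALSE)
  }
  I0 * (1 - (q * Rg)^2 / 3)
}

#' Power-law (fractal regime) intensity
#'
#' \eqn{I(q) = C q^{-D_f}}: the mass-fractal scattering law whose
#' log-log slope is exactly `-Df` everywhere.
#'
#' @param q Scattering vector(s), 1/um, strictly positive.
#' @param Df Fractal dimension (slope magnitude).
#' @param C Prefactor (> 0). Default 1.
#'
#' @return Intensity values.
#' @examples
#' fractal_intensity(10, Df = 2)      # 0.01
#' @export
fractal_intensity <- function(q, Df, C = 1) {
  stopifnot(is.numeric(q), is.numeric(Df), length(Df) == 1L,
            is.numeric(C), length(C) == 1L)
  if (any(q <= 0)) stop("`q` must be strictly positive", call. = FALSE)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  C * q^(-Df)
}

#' Porod (surface scattering) intensity
#'
#' \eqn{I(q) = C q^{-4}}: scattering from the smooth surfaces of the
#' primary particles at large `q`. Identical to
#' `fractal_intensity(q, Df = 4, C)`.
#'
#' @inheritParams fractal_intensity
#' @return Intensity values.
#' @examples
#' porod_intensity(2)   # 1/16
#' @export
porod_intensity <- function(q, C = 1) {
  fractal_intensity(q, Df = 4, C = C)
}

#' Rayleigh-Gans-Debye sphere form factor
#'
#' Exact RGD form factor of a homogeneous sphere of radius `R`,
#' \deqn{P(qR) = \left[\frac{3(\sin x - x \cos x)}{x^3}\right]^2, \quad
#'   x = qR,}
#' normalised so \eqn{P(0) = 1}. Serves as an independent closed-form
#' oracle: its small-`x` expansion reproduces the Guinier quadratic
#' coefficient (via \eqn{R_g^2 = 3R^2/5} for a sphere) and the log-log
#' slope of its large-`x` maxima envelope reproduces the Porod
#' exponent.
#'
#' @param q Scattering vector(s), 1/um, non-negative.
#' @param R Sphere radius, micrometres (> 0).
#'
#' @return Form-factor values in `[0, 1]`.
#' @examples
#' rgd_sphere_form_factor(c(0, 1, 4.4934), R = 1)
#' @export
rgd_sphere_form_factor <- function(q, R) {
  stopifnot(is.numeric(q), is.numeric(R), length(R) == 1L)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (any(q < 0)) stop("`q` must be non-negative", call. = FALSE)
  x <- q * R
  p <- numeric(length(x))
  # the direct formula cancels catastrophically at small x; use the
  # series 3(sin x - x cos x)/x^3 = 1 - x^2/10 + x^4/280 - x^6/15120 ...
  small <- x < 0.1
  xs <- x[small]
  p[small] <- (1 - xs^2 / 10 + xs^4 / 280 - xs^6 / 15120)^2
  xl <- x[!small]
  p[!small] <- (3 * (sin(xl) - xl * cos(xl)) / xl^3)^2
  p
}

#' Piecewise Guinier / power-law / Porod scattering curve
#'
#' Evaluates the three-regime forward model for a fractal aggregate on
#' a grid of scattering vectors: Guinier behaviour
#' (\eqn{I_0 e^{-q^2 R_g^2/3}}) up to the crossover \eqn{q_1 = 1/a},
#' the fractal power law \eqn{q^{-D_f}} between \eqn{q_1} and
#' \eqn{q_2 = 1/R_p}, and Porod \eqn{q^{-4}} beyond. The power-law and
#' Porod prefactors are rescaled so the curve is continuous at both
#' crossovers. The exponential Guinier form is used (rather than its
#' quadratic truncation) because flocs typically have \eqn{R_g > a},
#' where the truncated form would turn negative before the first
#' crossover; both forms agree where the truncation is valid.
#'
#' @param model An [aggregate_model()].
#' @param q Grid of scattering vectors (1/um), strictly increasing and
#'   positive; must start below `1/a` and end above `1/Rp` so all three
#'   regimes are represented.
#'
#' @return A [scattering_curve()], strictly positive and non-increasing.
#' @examples
#' m <- aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 2.26)
#' curve <- composite_intensity(m, q_log_grid(1e-3, 1e2, 200))
#' @export
composite_intensity <- function(model, q) {
  stopifnot(inherits(model, "aggregate_model"))
  if (!is.numeric(q) || length(q) < 2L || any(q <= 0) || any(diff(q) <= 0)) {
    stop("`q` must be positive, strictly increasing, length >= 2",
         call. = FALSE)
  }
  q1 <- 1 / model$a
  q2 <- 1 / model$Rp
  if (min(q) >= q1) {
    stop(sprintf(
      "grid must extend below the Guinier/power-law crossover 1/a = %.4g 1/um (grid starts at %.4g)",
      q1, min(q)), call. = FALSE)
  }
  if (max(q) <= q2) {
    stop(sprintf(
      "grid must extend above the power-law/Porod crossover 1/Rp = %.4g 1/um (grid ends at %.4g)",
      q2, max(q)), call. = FALSE)
  }
  # continuity: fractal prefactor matched at q1, Porod prefactor at q2
  C_frac <- model$I0 * exp(-(q1 * model$Rg)^2 / 3) * q1^model$Df
  C_porod <- C_frac * q2^(4 - model$Df)
  intensity <- ifelse(
    q <= q1, model$I0 * exp(-(q * model$Rg)^2 / 3),
    ifelse(q <= q2, C_frac * q^(-model$Df), C_porod * q^(-4))
  )
  scattering_curve(q, intensity)
}

#' Logarithmically spaced scattering-vector grid
#'
#' @param q_min,q_max Grid limits, 1/um (positive, `q_min < q_max`).
#' @param n Number of points (>= 2).
#' @return Numeric vector of `n` log-spaced values.
#' @examples
#' q_log_grid(1e-3, 1e2, 5)
#' @export
q_log_grid <- function(q_min, q_max, n = 200) {
  stopifnot(is.numeric(q_min), is.numeric(q_max), q_min > 0,
            q_max > q_min, n >= 2)
  g <- exp(seq(log(q_min), log(q_max), length.out = n))
  g[1] <- q_min          # pin endpoints against floating-point drift
  g[n] <- q_max
  g
}

#' Simulate a replicated noisy measurement of a scattering curve
#'
#' Emulates an instrument sweep averaged over repeated acquisitions:
#' each replicate multiplies every intensity by an independent
#' lognormal factor (median 1, log-sd `rel_noise_sd`) and the
#' replicates are averaged arithmetically per grid point, as an
#' averaging detector would. With `rel_noise_sd = 0` the input is
#' returned unchanged.
#'
#' @param curve A [scattering_curve()].
#' @param rel_noise_sd Log-scale standard deviation of the per-point
#'   multiplicative noise (>= 0). Default `0.02`.
#' @param n_reps Number of replicates averaged (>= 1). Default `15`,
#'   the usual repetition count of a granulometer measurement.
#' @param seed Integer seed; identical seeds give identical output. The
#'   caller's RNG state is left untouched.
#'
#' @return A [scattering_curve()] of averaged noisy intensities.
#' @examples
#' m <- aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 2.2)
#' clean <- composite_intensity(m, q_log_grid(1e-3, 1e2, 50))
#' noisy <- simulate_measurement(clean, rel_noise_sd = 0.02, seed = 1)
#' @export
simulate_measurement <- function(curve, rel_noise_sd = 0.02, n_reps = 15,
                                 seed = 1) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!is.numeric(rel_noise_sd) || length(rel_noise_sd) != 1L ||
      !is.finite(rel_noise_sd) || rel_noise_sd < 0) {
    stop("`rel_noise_sd` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    stop("`n_reps` must be >= 1", call. = FALSE)
  }
  if (rel_noise_sd == 0) return(curve)
  n_reps <- as.integer(n_reps)
  nq <- length(curve$q)
  mean_int <- with_seed(seed, {
    factors <- matrix(stats::rlnorm(nq * n_reps, meanlog = 0,
                                    sdlog = rel_noise_sd),
                      nrow = nq, ncol = n_reps)
    rowMeans(curve$intensity * factors)
  })
  scattering_curve(curve$q, mean_int)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
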