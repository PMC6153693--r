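#' Power-law regime bounds
#'
#' The scattering-vector window `[q_low, q_high]` over which a curve is
#' treated as a fractal power law. `q_low` estimates the reciprocal of
#' the largest non-Porod structure size (`1/a`) and `q_high` the
#' reciprocal primary-particle size (`1/Rp`).
#'
#' @param q_low,q_high Window limits in 1/um, `0 < q_low < q_high`.
#' @param n_points Number of grid points inside the window (>= 3).
#'
#' @return An object of class `regime_bounds`.
#' @examples
#' regime_bounds(0.05, 2, n_points = 40)
#' @export
regime_bounds <- function(q_low, q_high, n_points) {
  stopifnot(is.numeric(q_low), is.numeric(q_high), length(q_low) == 1L,
            length(q_high) == 1L)
  if (!(q_low > 0 && q_high > q_low)) {
    stop("need 0 < q_low < q_high", call. = FALSE)
  }
  if (n_points < 3) stop("`n_points` must be >= 3", call. = FALSE)
  structure(list(q_low = q_low, q_high = q_high,
                 n_points = as.integer(n_points)),
            class = "regime_bounds")
}

#' @export
print.regime_bounds <- function(x, ...) {
  cat(sprintf("Power-law regime: q in [%.4g, %.4g] 1/um (%d points)\n",
              x$q_low, x$q_high, x$n_points))
  invisible(x)
}

#' Ordinary least-squares power-law fit on a log-log curve
#'
#' Regresses `log10(intensity)` on `log10(q)` over the grid points that
#' fall inside `bounds`. The slope's standard error uses the residual
#' variance with `n - 2` degrees of freedom; for an exact power law the
#' standard error is zero and `r_squared` is one (a zero-variance
#' response is treated as perfectly fit).
#'
#' @param curve A [scattering_curve()] with positive intensities.
#' @param bounds A [regime_bounds()] window; at least three grid points
#'   must fall inside it.
#'
#' @return An object of class `power_law_fit`: list with `slope`,
#'   `intercept` (log10 scale), `slope_stderr`, `r_squared`, `n`, and
#'   the fitted window `q_low`, `q_high`.
#' @examples
#' q <- q_log_grid(0.01, 10, 50)
#' curve <- scattering_curve(q, q^-2.28)
#' fit_power_law(curve, regime_bounds(0.01, 10, 50))
#' @export
fit_power_law <- function(curve, bounds) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(bounds, "regime_bounds"))
  sel <- curve$q >= bounds$q_low & curve$q <= bounds$q_high
  n <- sum(sel)
  if (n < 3) {
    stop(sprintf("insufficient data: only %d grid points inside [%.4g, %.4g]; need >= 3",
                 n, bounds$q_low, bounds$q_high), call. = FALSE)
  }
  x <- log10(curve$q[sel])
  y <- log10(curve$intensity[sel])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  stderr <- sqrt(rss / (n - 2) / sxx)
  r2 <- if (tss <= .Machine$double.eps * n) 1 else max(0, min(1, 1 - rss / tss))
  structure(list(slope = slope, intercept = intercept,
                 slope_stderr = stderr, r_squared = r2, n = as.integer(n),
                 q_low = bounds$q_low, q_high = bounds$q_high),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: slope %.4f (se %.4g), r^2 = %.5f, n = %d\n",
              x$slope, x$slope_stderr, x$r_squared, x$n))
  invisible(x)
}

#' Student-t confidence-interval halfwidth for the fitted slope
#'
#' Halfwidth of the two-sided confidence interval for the regression
#' slope, \eqn{t_{(1+level)/2,\,n-2} \times \mathrm{se}(slope)}.
#'
#' @param fit A [fit_power_law()] result with `n >= 3`.
#' @param level Confidence level in `(0, 1)`. Default `0.95`.
#'
#' @return Non-negative halfwidth (dimensionless, same scale as the
#'   slope and hence as the fractal dimension).
#' @examples
#' q <- q_log_grid(0.1, 1, 10)
#' fit <- fit_power_law(scattering_curve(q, q^-2.2), regime_bounds(0.1, 1, 10))
#' student_t_ci(fit)
#' @export
student_t_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (fit$n < 3) stop("insufficient data: need n >= 3", call. = FALSE)
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop("`level` must lie in (0, 1)", call. = FALSE)
  }
  stats::qt((1 + level) / 2, df = fit$n - 2) * fit$slope_stderr
}

#' Detect the power-law (fractal) regime on a log-log curve
#'
#' Finds the longest contiguous window of grid points whose log-log OLS
#' fit has `r^2 >= r2_min` and whose per-point local slopes (centred
#' finite differences of `log10 I` against `log10 q` for interior
#' points; one-sided secants at the window ends, so the test never
#' looks outside the candidate window) all deviate from the window's
#' OLS slope by less than `slope_tol`. Windows whose fitted slope magnitude reaches
#' `max_slope` are rejected as Porod-like (surface scattering, exponent
#' 4) rather than fractal: a mass-fractal exponent cannot exceed 3, so
#' without this guard the large-q Porod branch — itself an exact power
#' law, and often the longest one on a wide grid — would be returned
#' instead of the fractal regime. Ties between equally long windows are
#' broken in favour of the smaller `q_low`. A curve with no qualifying
#' window (for example pure Guinier curvature throughout) raises an
#' error of class `flocscatter_no_regime`.
#'
#' @param curve A [scattering_curve()].
#' @param r2_min Minimum coefficient of determination for a window to
#'   qualify. Default `0.995`.
#' @param slope_tol Maximum allowed deviation of any local slope from
#'   the window slope. Default `0.15`.
#' @param min_points Minimum window length in grid points (>= 5).
#'   Default `8`.
#' @param max_slope Maximum admissible slope magnitude for a fractal
#'   window. Default `3.5`, between the physical ceiling of a mass
#'   fractal (3) and the Porod exponent (4).
#'
#' @return A [regime_bounds()] object.
#' @examples
#' m <- aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 2.2)
#' curve <- composite_intensity(m, q_log_grid(1e-3, 1e2, 200))
#' detect_power_law_regime(curve)
#' @export
detect_power_law_regime <- function(curve, r2_min = 0.995, slope_tol = 0.15,
                                    min_points = 8, max_slope = 3.5) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (min_points < 5) stop("`min_points` must be >= 5", call. = FALSE)
  if (!is.numeric(max_slope) || length(max_slope) != 1L || max_slope <= 0) {
    stop("`max_slope` must be a single positive number", call. = FALSE)
  }
  n <- length(curve$q)
  if (n < min_points) {
    stop(sprintf("curve has %d points; need at least min_points = %d",
                 n, min_points), call. = FALSE)
  }
  x <- log10(curve$q)
  y <- log10(curve$intensity)

  # centred local slopes (interior points) and adjacent secants (window ends)
  loc <- numeric(n)
  if (n > 2) {
    k <- 2:(n - 1)
    loc[k] <- (y[k + 1] - y[k - 1]) / (x[k + 1] - x[k - 1])
  }
  sec <- diff(y) / diff(x)

  # prefix sums for O(1) window OLS
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  psum <- function(c, i, j) c[j] - if (i > 1) c[i - 1] else 0

  best_i <- 0L; best_j <- 0L; best_len <- 0L
  for (i in seq_len(n - min_points + 1L)) {
    j <- (i + min_points - 1L):n
    m <- j - i + 1L
    sx <- psum(cx, i, j); sy <- psum(cy, i, j)
    sxx <- psum(cxx, i, j); sxy <- psum(cxy, i, j); syy <- psum(cyy, i, j)
    vxx <- sxx - sx^2 / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy^2 / m
    slope <- vxy / vxx
    r2 <- ifelse(vyy <= .Machine$double.eps * m, 1,
                 pmax(0, pmin(1, vxy^2 / (vxx * vyy))))
    # running envelope of centred slopes over the interior (i+1)..(j-1);
    # min_points >= 5 guarantees the interior is never empty
    seg <- loc[(i + 1L):(n - 1L)]
    idx <- j - i - 1L
    lmin <- cummin(seg)[idx]
    lmax <- cummax(seg)[idx]
    dev <- pmax(abs(lmin - slope), abs(lmax - slope),
                abs(sec[i] - slope), abs(sec[j - 1L] - slope))
    ok <- r2 >= r2_min & abs(slope) < max_slope & dev < slope_tol
    if (any(ok)) {
      jbest <- max(j[ok])
      len <- jbest - i + 1L
      if (len > best_len) {
        best_len <- len; best_i <- i; best_j <- jbest
      }
    }
  }
  if (best_len == 0L) {
    stop(structure(
      class = c("flocscatter_no_regime", "error", "condition"),
      list(message = paste0(
             "no power-law regime found: no contiguous window of >= ",
             min_points, " points satisfies r^2 >= ", r2_min,
             " with local slopes within ", slope_tol, " of the window slope"),
           call = sys.call(-1))))
  }
  regime_bounds(curve$q[best_i], curve$q[best_j], n_points = best_len)
}

#' Convert a scattering-vector magnitude to a particle diameter
#'
#' The regime limits `1/a <= q <= 1/Rp` identify length scales as
#' reciprocals of `q`; accordingly the default conversion is
#' `d = 1/q`. The alternative Bragg-like convention `d = 2*pi/q` is
#' available but never the default.
#'
#' @param q Scattering vector(s), 1/um, strictly positive.
#' @param convention `"reciprocal"` (default, `d = 1/q`) or `"two_pi"`
#'   (`d = 2*pi/q`).
#'
#' @return Diameter(s) in micrometres; strictly decreasing in `q`.
#' @examples
#' q_to_diameter(0.1)            # 10 um
#' @export
q_to_diameter <- function(q, convention = c("reciprocal", "two_pi")) {
  convention <- match.arg(convention)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0)) {
    stop("`q` must be strictly positive", call. = FALSE)
  }
  if (convention == "reciprocal") 1 / q else 2 * pi / q
}

#' Rayleigh-Gans-Debye validity flag for a particle diameter
#'
#' The RGD approximation requires scatterers much smaller than the
#' illumination wavelength (`d << lambda`); the implemented flag is the
#' strict comparison `d < lambda`. Fitted regimes routinely extend to
#' diameters of tens of micrometres, far beyond this nominal limit —
#' the flag makes that explicit rather than preventing the fit.
#'
#' @param d Diameter(s) in micrometres, positive.
#' @param optics An [optical_config()]; supplies the wavelength.
#'
#' @return Logical: `TRUE` where `d` is inside the nominal RGD domain.
#' @examples
#' rgd_validity_flag(c(0.1, 30), optical_config())
#' @export
rgd_validity_flag <- function(d, optics = optical_config()) {
  stopifnot(inherits(optics, "optical_config"))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be strictly positive", call. = FALSE)
  }
  d < optics$wavelength_um
}

#' Full fractal-dimension estimation pipeline
#'
#' Composes regime detection, log-log OLS fitting, the Student-t
#' confidence interval and the q-to-diameter conversion into a single
#' call: the standard workflow for extracting an optical fractal
#' dimension from a static light-scattering curve. The fractal
#' dimension is the negated slope; a value outside `(1, 3]` produces a
#' warning (physically suspect but reported as-is, since estimates
#' slightly below 2 or near regime edges are legitimate data).
#'
#' @param curve A [scattering_curve()].
#' @inheritParams detect_power_law_regime
#' @param level Confidence level for the Student-t interval. Default
#'   `0.95`.
#' @param optics An [optical_config()] for the RGD validity flags.
#' @param convention q-to-diameter convention, see [q_to_diameter()].
#'
#' @return An object of class `fd_result`: list with `fd`,
#'   `ci_halfwidth`, `level`, `bounds` ([regime_bounds()]), `fit`
#'   ([fit_power_law()] result), `d_min_um`, `d_max_um`,
#'   `rgd_valid_up_to_um`, `exceeds_rgd`.
#' @examples
#' m <- aggregate_model(Rg = 100, Rp = 0.5, a = 20, Df = 2.26)
#' curve <- composite_intensity(m, q_log_grid(1e-3, 1e2, 200))
#' fd_pipeline(curve)
#' @export
fd_pipeline <- function(curve, r2_min = 0.995, slope_tol = 0.15,
                        min_points = 8, max_slope = 3.5, level = 0.95,
                        optics = optical_config(),
                        convention = c("reciprocal", "two_pi")) {
  convention <- match.arg(convention)
  bounds <- detect_power_law_regime(curve, r2_min = r2_min,
                                    slope_tol = slope_tol,
                                    min_points = min_points,
                                    max_slope = max_slope)
  fit <- fit_power_law(curve, bounds)
  ci <- student_t_ci(fit, level = level)
  fd <- -fit$slope
  if (fd <= 1 || fd > 3) {
    warning(sprintf("fitted fractal dimension %.3f lies outside (1, 3]", fd),
            call. = FALSE)
  }
  d_min <- q_to_diameter(bounds$q_high, convention)
  d_max <- q_to_diameter(bounds$q_low, convention)
  structure(
    list(fd = fd, ci_halfwidth = ci, level = level, bounds = bounds,
         fit = fit, d_min_um = d_min, d_max_um = d_max,
         rgd_valid_up_to_um = optics$wavelength_um,
         exceeds_rgd = d_max >= optics$wavelength_um),
    class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat("Optical fractal dimension estimate\n")
  cat(sprintf("  FD = %.3f +/- %.3f (%d%% Student-t CI, n = %d, r^2 = %.5f)\n",
              x$fd, x$ci_halfwidth, round(100 * x$level), x$fit$n,
              x$fit$r_squared))
  cat(sprintf("  regime: q in [%.4g, %.4g] 1/um -> d in [%.3g, %.3g] um\n",
              x$bounds$q_low, x$bounds$q_high, x$d_min_um, x$d_max_um))
  cat(sprintf("  RGD nominal limit %.4g um: %s\n", x$rgd_valid_up_to_um,
              if (x$exceeds_rgd) "fitted range EXCEEDS the RGD limit"
              else "fitted range within the RGD limit"))
  invisible(x)
}
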