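#' Size grid for binned particle-size distributions
#'
#' A strictly increasing set of bin edges in micrometres. The
#' representative diameter of each bin is the geometric mean of its
#' edges, the natural centroid on the logarithmic grids used by laser
#' granulometers whose bins span decades.
#'
#' @param edges Bin edges in micrometres, strictly increasing, all
#'   positive, at least two.
#'
#' @return An object of class `size_grid`: list with `edges`,
#'   `representative` (geometric-mean diameters) and `n_bins`.
#' @examples
#' size_grid(c(1, 10, 100))
#' @export
size_grid <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2L || any(!is.finite(edges))) {
    stop("`edges` must be finite numeric of length >= 2", call. = FALSE)
  }
  if (any(edges <= 0)) stop("bin edges must be positive", call. = FALSE)
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  edges <- as.numeric(edges)
  nb <- length(edges) - 1L
  structure(list(edges = edges,
                 representative = sqrt(edges[-length(edges)] * edges[-1]),
                 n_bins = nb),
            class = "size_grid")
}

#' Default logarithmic size grid
#'
#' Logarithmically uniform bins over the working range of a laser
#' granulometer, 0.02 to 2000 micrometres.
#'
#' @param n_bins Number of bins. Default `100`.
#' @return A [size_grid()].
#' @examples
#' default_size_grid()
#' @export
default_size_grid <- function(n_bins = 100) {
  stopifnot(n_bins >= 1)
  size_grid(exp(seq(log(0.02), log(2000), length.out = n_bins + 1L)))
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("Size grid: %d bins over [%.4g, %.4g] um\n",
              x$n_bins, min(x$edges), max(x$edges)))
  invisible(x)
}

#' Binned particle-size distribution
#'
#' A vector of non-negative bin weights on a [size_grid()], carrying an
#' explicit basis: `"volume"` (fraction of total particle volume per
#' bin, the native output of laser diffraction) or `"number"` (fraction
#' of particle count per bin). Weights are normalised to sum to one.
#'
#' @param grid A [size_grid()].
#' @param weights Non-negative weights, one per bin, with positive sum.
#' @param basis `"volume"` or `"number"`.
#'
#' @return An object of class `size_distribution`.
#' @examples
#' g <- size_grid(c(1, 10, 100))
#' size_distribution(g, c(0.3, 0.7), basis = "volume")
#' @export
size_distribution <- function(grid, weights, basis = c("volume", "number")) {
  stopifnot(inherits(grid, "size_grid"))
  basis <- match.arg(basis)
  if (!is.numeric(weights) || length(weights) != grid$n_bins ||
      any(!is.finite(weights))) {
    stop("`weights` must be finite numeric with one value per bin",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  tot <- sum(weights)
  if (tot <= 0) {
    stop("degenerate distribution: total weight is zero", call. = FALSE)
  }
  structure(list(grid = grid, weights = as.numeric(weights) / tot,
                 basis = basis),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  occ <- which(x$weights > 0)
  cat(sprintf("Particle-size distribution (%s basis): %d bins, occupied %.4g-%.4g um\n",
              x$basis, x$grid$n_bins,
              x$grid$edges[min(occ)], x$grid$edges[max(occ) + 1L]))
  invisible(x)
}

#' Flat list of particle diameters
#'
#' Equivalent-circle diameters, one per detected particle, as produced
#' by automated static image analysis. May be empty.
#'
#' @param diameters_um Numeric vector of positive diameters (um).
#' @return An object of class `particle_list`.
#' @examples
#' particle_list(c(1.04, 5.2, 245.7))
#' @export
particle_list <- function(diameters_um = numeric(0)) {
  if (!is.numeric(diameters_um) || any(!is.finite(diameters_um))) {
    stop("`diameters_um` must be finite numeric", call. = FALSE)
  }
  if (any(diameters_um <= 0)) {
    stop("all diameters must be positive", call. = FALSE)
  }
  structure(list(diameters_um = as.numeric(diameters_um)),
            class = "particle_list")
}

#' @export
print.particle_list <- function(x, ...) {
  n <- length(x$diameters_um)
  if (n == 0) cat("Particle list: empty\n")
  else cat(sprintf("Particle list: %d particles, %.3g-%.3g um\n",
                   n, min(x$diameters_um), max(x$diameters_um)))
  invisible(x)
}

#' Convert a size distribution between volume and number basis
#'
#' Applies the cubic bridge between volume and number weighting: the
#' number of particles in a bin is proportional to its volume weight
#' divided by the cube of the representative diameter
#' (\eqn{n_i \propto v_i / d_i^3}), and conversely
#' \eqn{v_i \propto n_i d_i^3}. Weights are renormalised after
#' conversion; converting to the distribution's own basis is the
#' identity, and a volume-number round trip restores the input exactly
#' (the two conversions are exact inverses on a shared grid).
#'
#' @param dist A [size_distribution()].
#' @param target_basis `"volume"` or `"number"`.
#'
#' @return A [size_distribution()] on the same grid in the target basis.
#' @examples
#' g <- size_grid(c(1, 10, 100))
#' v <- size_distribution(g, c(0.5, 0.5), basis = "volume")
#' reweight(v, "number")
#' @export
reweight <- function(dist, target_basis = c("volume", "number")) {
  stopifnot(inherits(dist, "size_distribution"))
  target_basis <- match.arg(target_basis)
  if (dist$basis == target_basis) return(dist)
  d3 <- dist$grid$representative^3
  w <- if (target_basis == "number") dist$weights / d3 else dist$weights * d3
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    stop("degenerate distribution after basis conversion", call. = FALSE)
  }
  size_distribution(dist$grid, w / tot, basis = target_basis)
}

#' Weight fraction within a diameter range
#'
#' Sum of bin weights falling in `[d_lo, d_hi)`. Bins lying entirely
#' inside the range contribute fully; a bin straddling a cut
#' contributes pro rata by the overlapped share of its logarithmic
#' width, so range fractions can be evaluated at cuts (such as 10 um)
#' that need not coincide with instrument bin edges.
#'
#' @param dist A [size_distribution()].
#' @param d_lo,d_hi Range limits in micrometres, `d_lo < d_hi`.
#'
#' @return Fraction in `[0, 1]`.
#' @examples
#' g <- default_size_grid()
#' v <- generate_psd(grid = g)
#' fraction_between(v, 10, max(g$edges))
#' @export
fraction_between <- function(dist, d_lo, d_hi) {
  stopifnot(inherits(dist, "size_distribution"),
            is.numeric(d_lo), is.numeric(d_hi),
            length(d_lo) == 1L, length(d_hi) == 1L)
  if (!(d_lo < d_hi)) stop("need d_lo < d_hi", call. = FALSE)
  if (d_hi <= 0) return(0)
  d_lo <- max(d_lo, .Machine$double.xmin)
  e <- log(dist$grid$edges)
  lo <- e[-length(e)]
  hi <- e[-1]
  ov_lo <- pmax(lo, log(d_lo))
  ov_hi <- pmin(hi, log(d_hi))
  frac <- pmax(0, ov_hi - ov_lo) / (hi - lo)
  f <- sum(dist$weights * frac)
  min(max(f, 0), 1)
}

#' Percentile diameter of a size distribution
#'
#' Diameter at which the cumulative weight reaches probability `p`,
#' interpolating log-linearly within bins (weight assumed uniform in
#' `log d` inside a bin). `percentile_diameter(dist, 0.5)` is the
#' median representative diameter d50 of granulometry reports.
#'
#' @param dist A [size_distribution()].
#' @param p Probability in `(0, 1)`; may be a vector.
#'
#' @return Diameter(s) in micrometres, non-decreasing in `p`.
#' @examples
#' v <- generate_psd()
#' percentile_diameter(v, c(0.1, 0.5, 0.9))
#' @export
percentile_diameter <- function(dist, p) {
  stopifnot(inherits(dist, "size_distribution"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  e <- log(dist$grid$edges)
  cum <- c(0, cumsum(dist$weights))
  vapply(p, function(pp) {
    k <- findInterval(pp, cum, rightmost.closed = TRUE)
    k <- min(max(k, 1L), dist$grid$n_bins)
    # skip empty bins the cumulative jumps over
    while (dist$weights[k] == 0 && k < dist$grid$n_bins && cum[k + 1] < pp) {
      k <- k + 1L
    }
    if (dist$weights[k] == 0) {
      return(exp(e[k]))
    }
    frac <- (pp - cum[k]) / dist$weights[k]
    exp(e[k] + frac * (e[k + 1] - e[k]))
  }, numeric(1))
}

#' Count particles in diameter bands
#'
#' Tallies a [particle_list()] into half-open bands delimited by
#' `band_edges`: below the first edge, `[e_k, e_{k+1})` between
#' consecutive edges, and at or above the last edge. The image-analysis
#' convention of reporting "< 10 um", "10-100 um" and ">= 100 um"
#' corresponds to `band_edges = c(10, 100)`. Counts always sum to the
#' list length; an empty list gives all-zero counts.
#'
#' @param particles A [particle_list()].
#' @param band_edges Strictly increasing positive diameters (um).
#'
#' @return Named integer vector of length `length(band_edges) + 1`.
#' @examples
#' band_counts(particle_list(c(5, 50, 500)), c(10, 100))
#' @export
band_counts <- function(particles, band_edges = c(10, 100)) {
  stopifnot(inherits(particles, "particle_list"))
  if (!is.numeric(band_edges) || length(band_edges) < 1L ||
      any(!is.finite(band_edges)) || any(band_edges <= 0)) {
    stop("`band_edges` must be positive numeric", call. = FALSE)
  }
  if (any(diff(band_edges) <= 0)) {
    stop("`band_edges` must be strictly increasing", call. = FALSE)
  }
  idx <- findInterval(particles$diameters_um, band_edges)
  counts <- tabulate(idx + 1L, nbins = length(band_edges) + 1L)
  labs <- c(sprintf("<%g", band_edges[1]),
            if (length(band_edges) > 1)
              sprintf("[%g,%g)", band_edges[-length(band_edges)],
                      band_edges[-1]),
            sprintf(">=%g", band_edges[length(band_edges)]))
  stats::setNames(as.integer(counts), labs)
}

#' Extrema and count of a particle list
#'
#' @param particles A non-empty [particle_list()].
#' @return List with `min_um`, `max_um`, `count`.
#' @examples
#' summary_stats(particle_list(c(1.04, 60, 245.72)))
#' @export
summary_stats <- function(particles) {
  stopifnot(inherits(particles, "particle_list"))
  if (length(particles$diameters_um) == 0L) {
    stop("empty particle list: no summary statistics", call. = FALSE)
  }
  list(min_um = min(particles$diameters_um),
       max_um = max(particles$diameters_um),
       count = length(particles$diameters_um))
}
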