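#' Default lognormal modes of the synthetic volume-basis PSD
#'
#' Two-mode calibration emulating the granulometric structure of
#' activated sludge: a dominant macrofloc mode peaking near 100 um that
#' carries essentially all of the particle volume, plus a microfloc
#' mode near 4 um that is invisible on the volume basis yet dominates
#' the particle count once the distribution is reweighted to number
#' basis (the cubic conversion amplifies small diameters by `1/d^3`).
#' The microfloc volume weight of 0.001 is the calibration constant:
#' under the exact cubic bridge it places about 90% of the particle
#' number below 10 um while keeping more than 96% of the volume above
#' 10 um.
#'
#' @return Data frame with columns `median_um`, `sdlog10`,
#'   `vol_weight` (one row per mode; weights sum to 1).
#' @examples
#' default_psd_modes()
#' @export
default_psd_modes <- function() {
  data.frame(
    median_um = c(100, 4),
    sdlog10 = c(0.30, 0.25),
    vol_weight = c(0.999, 0.001)
  )
}

#' Generate a calibrated synthetic volume-basis PSD
#'
#' Deterministic (no sampling): each bin receives the analytic mass of
#' a mixture of lognormal volume modes, integrated between the bin
#' edges and renormalised over the grid. The default modes are
#' calibrated so that the volume fraction above 10 um exceeds 96% and
#' the number fraction below 10 um (after [reweight()]) falls near 90%.
#'
#' @param modes Data frame with columns `median_um` (mode median, um),
#'   `sdlog10` (standard deviation of `log10` diameter) and
#'   `vol_weight` (volume weight of the mode; weights must sum to 1).
#'   Default [default_psd_modes()].
#' @param grid A [size_grid()]; every mode median must lie inside it.
#'
#' @return A volume-basis [size_distribution()].
#' @examples
#' v <- generate_psd()
#' fraction_between(v, 10, 2000)
#' @export
generate_psd <- function(modes = default_psd_modes(),
                         grid = default_size_grid()) {
  stopifnot(inherits(grid, "size_grid"))
  req <- c("median_um", "sdlog10", "vol_weight")
  if (!is.data.frame(modes) || !all(req %in% names(modes)) ||
      nrow(modes) < 1L) {
    stop("`modes` must be a data frame with columns median_um, sdlog10, vol_weight",
         call. = FALSE)
  }
  if (any(modes$median_um <= 0) || any(modes$sdlog10 <= 0) ||
      any(modes$vol_weight < 0)) {
    stop("mode parameters must be positive (weights non-negative)",
         call. = FALSE)
  }
  if (abs(sum(modes$vol_weight) - 1) > 1e-6) {
    stop("mode volume weights must sum to 1", call. = FALSE)
  }
  span <- range(grid$edges)
  if (any(modes$median_um <= span[1] | modes$median_um >= span[2])) {
    stop(sprintf("all mode medians must lie inside the grid span [%.4g, %.4g] um",
                 span[1], span[2]), call. = FALSE)
  }
  edges <- grid$edges
  w <- numeric(grid$n_bins)
  for (m in seq_len(nrow(modes))) {
    sdlog <- modes$sdlog10[m] * log(10)
    cdf <- stats::plnorm(edges, meanlog = log(modes$median_um[m]),
                         sdlog = sdlog)
    w <- w + modes$vol_weight[m] * diff(cdf)
  }
  size_distribution(grid, w, basis = "volume")
}

#' Sample individual particle diameters from a number-basis PSD
#'
#' Draws `n` independent diameters from a binned number-basis
#' distribution: bins are chosen with probability equal to their
#' weight, then a diameter is drawn log-uniformly within the bin
#' (consistent with the logarithmic grid). Emulates the per-particle
#' records of automated image analysis.
#'
#' @param dist A number-basis [size_distribution()]; a volume-basis
#'   input is rejected (convert with [reweight()] first).
#' @param n Number of particles to draw (>= 0).
#' @param seed Integer seed; identical seeds give identical lists.
#'
#' @return A [particle_list()] of `n` diameters.
#' @examples
#' num <- reweight(generate_psd(), "number")
#' sample_particles(num, 5, seed = 1)
#' @export
sample_particles <- function(dist, n, seed = 1) {
  stopifnot(inherits(dist, "size_distribution"))
  if (dist$basis != "number") {
    stop("`dist` must be on the number basis; convert with reweight(dist, \"number\") first",
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    stop("`n` must be a single non-negative count", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) return(particle_list(numeric(0)))
  e <- log(dist$grid$edges)
  d <- with_seed(seed, {
    bins <- sample.int(dist$grid$n_bins, size = n, replace = TRUE,
                       prob = dist$weights)
    u <- stats::runif(n)
    exp(e[bins] + u * (e[bins + 1L] - e[bins]))
  })
  particle_list(d)
}

#' Generate one synthetic noisy scattering measurement with known truth
#'
#' Composes [composite_intensity()] and [simulate_measurement()] on a
#' default 200-point log grid spanning q in `[1e-3, 1e2]` 1/um, and
#' returns the curve together with a truth record echoing the
#' generating parameters, so estimator recovery can be scored exactly.
#'
#' @param Df Generating fractal dimension, in `(1, 3]`.
#' @param Rg Radius of gyration, um. Default 100.
#' @param Rp Primary-particle size, um. Default 0.7.
#' @param a Largest non-Porod size, um. Default 25.
#' @param rel_noise_sd Lognormal noise log-sd. Default 0.02.
#' @param n_reps Replicates averaged. Default 15.
#' @param seed Integer seed.
#' @param n_q Grid points. Default 200.
#' @param q_range Grid limits, 1/um. Default `c(1e-3, 1e2)`.
#'
#' @return List with elements `curve` (a [scattering_curve()]) and
#'   `truth` (list of the generating parameters).
#' @examples
#' s <- generate_scattering_sample(Df = 2.2, seed = 1)
#' fd_pipeline(s$curve)$fd
#' @export
generate_scattering_sample <- function(Df, Rg = 100, Rp = 0.7, a = 25,
                                       rel_noise_sd = 0.02, n_reps = 15,
                                       seed = 1, n_q = 200,
                                       q_range = c(1e-3, 1e2)) {
  model <- aggregate_model(Rg = Rg, Rp = Rp, a = a, Df = Df)
  grid <- q_log_grid(q_range[1], q_range[2], n_q)
  clean <- composite_intensity(model, grid)
  curve <- simulate_measurement(clean, rel_noise_sd = rel_noise_sd,
                                n_reps = n_reps, seed = seed)
  list(curve = curve,
       truth = list(Df = Df, Rg = Rg, Rp = Rp, a = a,
                    rel_noise_sd = rel_noise_sd, n_reps = n_reps,
                    seed = seed))
}

#' Generate a synthetic multi-sample study ensemble
#'
#' Desk-scale stand-in for a sampling campaign across several
#' treatment plants: `n_samples` scattering curves whose generating
#' fractal dimensions are drawn uniformly from `fd_range` and whose
#' structural sizes are drawn uniformly from ranges typical of
#' activated-sludge flocs (Rg 50-150 um, Rp 0.4-1.0 um, a 10-45 um).
#'
#' @param n_samples Number of samples. Default 69.
#' @param fd_range Lower and upper generating fractal dimension.
#'   Default `c(1.98, 2.34)`.
#' @param rel_noise_sd,n_reps Measurement-noise model, as in
#'   [simulate_measurement()].
#' @param seed Master integer seed; parameter draws and per-sample
#'   noise all derive from it.
#'
#' @return List of `n_samples` elements, each as returned by
#'   [generate_scattering_sample()].
#' @examples
#' ens <- generate_study_ensemble(n_samples = 3, seed = 1)
#' sapply(ens, function(s) s$truth$Df)
#' @export
generate_study_ensemble <- function(n_samples = 69,
                                    fd_range = c(1.98, 2.34),
                                    rel_noise_sd = 0.02, n_reps = 15,
                                    seed = 1) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(fd_range) || length(fd_range) != 2L ||
      !(1 < fd_range[1] && fd_range[1] < fd_range[2] && fd_range[2] <= 3)) {
    stop("`fd_range` must satisfy 1 < low < high <= 3", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  pars <- with_seed(seed, {
    list(Df = stats::runif(n_samples, fd_range[1], fd_range[2]),
         Rg = stats::runif(n_samples, 50, 150),
         Rp = stats::runif(n_samples, 0.4, 1.0),
         a = stats::runif(n_samples, 10, 45),
         sub_seed = sample.int(.Machine$integer.max - 1L, n_samples))
  })
  lapply(seq_len(n_samples), function(i) {
    generate_scattering_sample(Df = pars$Df[i], Rg = pars$Rg[i],
                               Rp = pars$Rp[i], a = pars$a[i],
                               rel_noise_sd = rel_noise_sd,
                               n_reps = n_reps, seed = pars$sub_seed[i])
  })
}
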