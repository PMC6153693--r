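#' Run the full floc-characterisation analysis and write a JSON report
#'
#' End-to-end driver mirroring a complete sample work-up: one or more
#' scattering curves are run through [fd_pipeline()]; a binned PSD is
#' converted to both bases and summarised by range fractions and
#' percentile diameters; a particle list is tallied into size bands.
#' Any combination of the three inputs may be supplied. The report is
#' deterministic given fixed inputs and parameters, numbers are
#' serialised at full precision, and units are embedded in key names.
#'
#' @param curve_files Character vector of scattering-curve CSV paths
#'   (may be empty).
#' @param psd_file Optional PSD CSV path.
#' @param particle_file Optional particle-list CSV path.
#' @param out Optional path for the JSON report; `NULL` skips writing.
#' @param cut_um Diameter cut for PSD range fractions. Default 10.
#' @param band_edges_um Band edges for particle counting. Default
#'   `c(10, 100)`.
#' @param level Confidence level for fractal-dimension intervals.
#' @param r2_min,slope_tol,min_points Regime-detection parameters, see
#'   [detect_power_law_regime()].
#' @param optics An [optical_config()].
#'
#' @return The report as a list (invisibly if `out` is given).
#' @examples
#' s <- generate_scattering_sample(Df = 2.2, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_scattering_curve(s$curve, f)
#' rep <- run_full_analysis(curve_files = f)
#' rep$fd_results[[1]]$fd
#' @export
run_full_analysis <- function(curve_files = character(0),
                              psd_file = NULL, particle_file = NULL,
                              out = NULL, cut_um = 10,
                              band_edges_um = c(10, 100), level = 0.95,
                              r2_min = 0.995, slope_tol = 0.15,
                              min_points = 8, optics = optical_config()) {
  if (length(curve_files) == 0 && is.null(psd_file) &&
      is.null(particle_file)) {
    stop("no inputs: supply at least one of curve_files, psd_file, particle_file",
         call. = FALSE)
  }
  report <- list(schema = 1L)

  if (length(curve_files) > 0) {
    report$fd_results <- lapply(curve_files, function(f) {
      curve <- read_scattering_curve(f, optics)
      res <- fd_pipeline(curve, r2_min = r2_min, slope_tol = slope_tol,
                         min_points = min_points, level = level,
                         optics = optics)
      list(input = f, fd = res$fd, ci_halfwidth = res$ci_halfwidth,
           level = res$level, q_low_per_um = res$bounds$q_low,
           q_high_per_um = res$bounds$q_high,
           d_min_um = res$d_min_um, d_max_um = res$d_max_um,
           exceeds_rgd = res$exceeds_rgd, n_points = res$fit$n,
           r_squared = res$fit$r_squared)
    })
  }

  if (!is.null(psd_file)) {
    dist <- read_psd(psd_file)
    vol <- reweight(dist, "volume")
    num <- reweight(dist, "number")
    gmin <- min(dist$grid$edges)
    gmax <- max(dist$grid$edges)
    report$psd <- list(
      input = psd_file, input_basis = dist$basis,
      cut_um = cut_um,
      volume_fraction_below_cut = fraction_between(vol, gmin, cut_um),
      volume_fraction_above_cut = fraction_between(vol, cut_um, gmax),
      number_fraction_below_cut = fraction_between(num, gmin, cut_um),
      number_fraction_above_cut = fraction_between(num, cut_um, gmax),
      volume_d10_um = percentile_diameter(vol, 0.1),
      volume_d50_um = percentile_diameter(vol, 0.5),
      volume_d90_um = percentile_diameter(vol, 0.9),
      number_d50_um = percentile_diameter(num, 0.5))
  }

  if (!is.null(particle_file)) {
    particles <- read_particle_list(particle_file)
    counts <- band_counts(particles, band_edges_um)
    report$particles <- list(
      input = particle_file, band_edges_um = band_edges_um,
      band_counts = as.list(counts),
      count = length(particles$diameters_um))
    if (length(particles$diameters_um) > 0) {
      ss <- summary_stats(particles)
      report$particles$min_um <- ss$min_um
      report$particles$max_um <- ss$max_um
    }
  }

  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
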