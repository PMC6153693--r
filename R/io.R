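#' Read a scattering curve from CSV
#'
#' Accepts either of two dialects: columns `q_per_um,intensity`
#' (scattering vector already computed) or `angle_deg,intensity`
#' (detector angles, converted via [q_from_angle()] with the supplied
#' optics). Lines starting with `#` are comments. Rows are sorted by
#' `q`; duplicate q values are rejected.
#'
#' @param path CSV file path.
#' @param optics An [optical_config()], used only for the angle dialect.
#'
#' @return A [scattering_curve()].
#' @export
read_scattering_curve <- function(path, optics = optical_config()) {
  df <- read_csv_checked(path, alternatives = list(
    c("q_per_um", "intensity"),
    c("angle_deg", "intensity")
  ))
  q <- if ("q_per_um" %in% names(df)) {
    df$q_per_um
  } else {
    q_from_angle(df$angle_deg, optics)
  }
  ord <- order(q)
  q <- q[ord]
  if (any(diff(q) == 0)) {
    stop(sprintf("duplicate q values in '%s'", path), call. = FALSE)
  }
  scattering_curve(q, df$intensity[ord])
}

#' Write a scattering curve to CSV
#'
#' Writes the `q_per_um,intensity` dialect with a `#` comment header.
#'
#' @param curve A [scattering_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scattering_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# static light-scattering curve (relative intensity)", con)
  writeLines("q_per_um,intensity", con)
  utils::write.table(
    data.frame(q = curve$q, i = curve$intensity), con, sep = ",",
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned particle-size distribution from CSV
#'
#' Dialect: columns `edge_low_um,edge_high_um,weight`, one row per bin,
#' with contiguous bins (each `edge_low_um` equal to the previous
#' `edge_high_um`), plus a comment line `# basis=volume` or
#' `# basis=number` declaring the weighting basis.
#'
#' @param path CSV file path.
#' @return A [size_distribution()].
#' @export
read_psd <- function(path) {
  basis <- NA_character_
  for (line in readLines(path, warn = FALSE)) {
    m <- regmatches(line, regexec("^#\\s*basis\\s*=\\s*(volume|number)\\s*$",
                                  line))[[1]]
    if (length(m) == 2L) basis <- m[2]
  }
  if (is.na(basis)) {
    stop(sprintf("'%s' lacks the required '# basis=volume|number' comment",
                 path), call. = FALSE)
  }
  df <- read_csv_checked(path, alternatives = list(
    c("edge_low_um", "edge_high_um", "weight")))
  ord <- order(df$edge_low_um)
  df <- df[ord, ]
  if (any(abs(df$edge_low_um[-1] - df$edge_high_um[-nrow(df)]) >
          1e-9 * df$edge_high_um[-nrow(df)])) {
    stop(sprintf("bins in '%s' are not contiguous", path), call. = FALSE)
  }
  grid <- size_grid(c(df$edge_low_um, df$edge_high_um[nrow(df)]))
  size_distribution(grid, df$weight, basis = basis)
}

#' Write a binned particle-size distribution to CSV
#'
#' @param dist A [size_distribution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# basis=%s", dist$basis), con)
  writeLines("edge_low_um,edge_high_um,weight", con)
  e <- dist$grid$edges
  utils::write.table(
    data.frame(lo = e[-length(e)], hi = e[-1], w = dist$weights), con,
    sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a flat particle list from CSV
#'
#' Dialect: single column `diameter_um`, one particle per row; `#`
#' comments allowed. An empty data section yields an empty list.
#'
#' @param path CSV file path.
#' @return A [particle_list()].
#' @export
read_particle_list <- function(path) {
  df <- read_csv_checked(path, alternatives = list("diameter_um"),
                         allow_empty = TRUE)
  particle_list(df$diameter_um)
}

#' Write a flat particle list to CSV
#'
#' @param particles A [particle_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_particle_list <- function(particles, path) {
  stopifnot(inherits(particles, "particle_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("diameter_um", con)
  if (length(particles$diameters_um) > 0) {
    writeLines(format(particles$diameters_um, digits = 15, trim = TRUE,
                      scientific = FALSE), con)
  }
  invisible(path)
}

# Shared CSV reader: `#` comments, required column sets, numeric
# coercion with named-line diagnostics.
read_csv_checked <- function(path, alternatives, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) {
      stop(sprintf("cannot parse '%s' as CSV: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  match_idx <- which(vapply(alternatives,
                            function(cols) all(cols %in% names(df)),
                            logical(1)))
  if (length(match_idx) == 0L) {
    stop(sprintf(
      "'%s' lacks required columns; expected one of: %s (found: %s)",
      path,
      paste(vapply(alternatives, paste, "", collapse = ","),
            collapse = " | "),
      paste(names(df), collapse = ",")), call. = FALSE)
  }
  cols <- alternatives[[match_idx[1]]]
  if (nrow(df) == 0L && !allow_empty) {
    stop(sprintf("'%s' contains no data rows", path), call. = FALSE)
  }
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(v))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(sprintf("non-numeric value in column '%s' of '%s' (data row %d)",
                     cl, path, bad), call. = FALSE)
      }
      df[[cl]] <- v
    }
    if (anyNA(df[[cl]])) {
      stop(sprintf("missing value in column '%s' of '%s'", cl, path),
           call. = FALSE)
    }
  }
  df[, cols, drop = FALSE]
}
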