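# CSV I/O. Dialect: comma-separated UTF-8, mandatory header, metadata in
# leading comment lines of the form "# key: value". Degrees and nm at the
# file boundary; mm and mm^-1 everywhere inside the package.

parse_meta_lines <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

read_csv_with_meta <- function(path, required_cols, suggestion) {
  if (!file.exists(path))
    top_error(sprintf("File not found: %s", path), "tendonoptics_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_lines(lines)
  body_idx <- grep("^\\s*#", lines, invert = TRUE)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) < 2)
    top_error(sprintf("%s: no data rows found.", path), "tendonoptics_parse_error")
  header_line <- body_idx[1]
  df <- tryCatch(
    read.csv(text = paste(lines[body_idx], collapse = "\n"),
             check.names = FALSE, colClasses = NA),
    error = function(e)
      top_error(sprintf("%s: %s", path, conditionMessage(e)),
                "tendonoptics_parse_error"))
  cols <- names(df)
  if (!all(required_cols %in% cols))
    top_error(sprintf(
      "%s: header is `%s` but columns `%s` are required%s.",
      path, paste(cols, collapse = ","), paste(required_cols, collapse = ","),
      if (nzchar(suggestion)) paste0(" (did you mean `", suggestion, "`?)") else ""),
      "tendonoptics_parse_error")
  if (anyDuplicated(cols))
    top_error(sprintf("%s: duplicate columns in header.", path),
              "tendonoptics_parse_error")
  for (cc in required_cols) {
    v <- df[[cc]]
    numeric_v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(numeric_v))
    if (length(bad))
      top_error(sprintf("%s: non-numeric value '%s' in column `%s` at line %d.",
                        path, v[bad[1]], cc, header_line + bad[1]),
                "tendonoptics_parse_error")
    df[[cc]] <- numeric_v
  }
  list(df = df, meta = meta)
}

#' Read / write goniometer angular scans (CSV)
#'
#' The file format is `theta_deg,intensity` with optional metadata comment
#' lines (`# wavelength_nm: 633`, `# orientation: transverse`,
#' `# condition: saline`). Rows with shuffled angles are sorted with a
#' warning. A directory of such files constitutes a replicate group; see
#' [read_scan_group()].
#'
#' @param path file path.
#' @return an [angular_scan()].
#' @export
read_angular_csv <- function(path) {
  out <- read_csv_with_meta(path, c("theta_deg", "intensity"),
                            "theta_deg,intensity")
  m <- out$meta
  angular_scan(out$df$theta_deg, out$df$intensity,
               wavelength_nm = m$wavelength_nm %||% 633,
               orientation = as.character(m$orientation %||% NA),
               condition = as.character(m$condition %||% NA))
}

#' @rdname read_angular_csv
#' @param scan an [angular_scan()] to write.
#' @export
write_angular_csv <- function(scan, path) {
  stopifnot(inherits(scan, "angular_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# wavelength_nm: %g", scan$wavelength_nm),
               sprintf("# orientation: %s", scan$orientation),
               sprintf("# condition: %s", scan$condition),
               "theta_deg,intensity"), con)
  writeLines(sprintf("%.10g,%.10g", scan$theta_deg, scan$intensity), con)
  invisible(path)
}

#' Read and average a directory of replicate scans
#'
#' Reads every `*.csv` under `dir` as an angular scan and averages them on
#' their common grid, the standard preparation before phase-function
#' fitting.
#'
#' @param dir directory of scan CSV files.
#' @return an [angular_scan()] holding the replicate mean.
#' @export
read_scan_group <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0)
    top_error(sprintf("No CSV files in %s.", dir), "tendonoptics_io_error")
  average_scans(lapply(files, read_angular_csv))
}

#' Read / write integrating-sphere spectra (CSV)
#'
#' Format: `wavelength_nm,Rd,Tt` with metadata comment lines; the
#' `# thickness_mm:` entry is mandatory on read because the inversion cannot
#' proceed without the slab thickness.
#'
#' @param path file path.
#' @return a [spectrum_measurement()].
#' @export
read_spectra_csv <- function(path) {
  out <- read_csv_with_meta(path, c("wavelength_nm", "Rd", "Tt"),
                            "wavelength_nm,Rd,Tt")
  m <- out$meta
  if (is.null(m$thickness_mm))
    top_error(sprintf("%s: missing `# thickness_mm:` metadata line.", path),
              "tendonoptics_parse_error")
  spectrum_measurement(out$df$wavelength_nm, out$df$Rd, out$df$Tt,
                       thickness_mm = m$thickness_mm,
                       orientation = as.character(m$orientation %||% NA),
                       condition = as.character(m$condition %||% NA))
}

#' @rdname read_spectra_csv
#' @param meas a [spectrum_measurement()] to write.
#' @export
write_spectra_csv <- function(meas, path) {
  stopifnot(inherits(meas, "spectrum_measurement"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# thickness_mm: %g", meas$thickness_mm),
               sprintf("# orientation: %s", meas$orientation),
               sprintf("# condition: %s", meas$condition),
               "wavelength_nm,Rd,Tt"), con)
  writeLines(sprintf("%.10g,%.10g,%.10g", meas$wavelength_nm, meas$Rd,
                     meas$Tt), con)
  invisible(path)
}

#' Read a transmission-scenario configuration (YAML)
#'
#' Expected structure: top-level `photons`, `seed`, optional `geometry`
#' (`dims`, `voxel`, `beam_diameter`, `boundary`, `n_ambient`) and one or
#' more named `scenarios`, each with `mua`, `g`, `n` and either `mus` or
#' `musp`.
#'
#' @param path YAML file path.
#' @return a named list of [transmission_scenario()] objects.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    top_error(sprintf("Config not found: %s", path), "tendonoptics_io_error")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    top_error("Config must define at least one entry under `scenarios`.",
              "tendonoptics_parse_error")
  gdef <- cfg$geometry %||% list()
  geom <- volume_geometry(
    dims = as.numeric(gdef$dims %||% c(13.8, 13.8, 50)),
    voxel = gdef$voxel %||% 0.2,
    beam_diameter = gdef$beam_diameter %||% 0.2,
    boundary = gdef$boundary %||% "fresnel",
    n_ambient = gdef$n_ambient %||% 1.0)
  lapply(setNames(names(cfg$scenarios), names(cfg$scenarios)), function(nm) {
    sc <- cfg$scenarios[[nm]]
    props <- optical_properties(mua = sc[["mua"]], mus = sc[["mus"]],
                                g = sc[["g"]] %||% 0, n = sc[["n"]] %||% 1.40,
                                musp = sc[["musp"]])
    transmission_scenario(props, geom,
                          n_photons = cfg$photons %||% 1e5,
                          seed = cfg$seed %||% 1, label = nm)
  })
}
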