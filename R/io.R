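# Plain-text readers and writers for the package's file dialects, and the
# thermodynamics report renderer.

#' Read a titration peak list
#'
#' Two dialects: `"sparky"` — a Sparky-style `.list` file with an
#' `Assignment w1 w2` header and columns label, 15N ppm, 1H ppm; and
#' `"csv"` — a CSV with header `residue,h_ppm,n_ppm`. `"auto"` picks CSV for
#' a `.csv` extension, Sparky otherwise. Labels are kept verbatim (including
#' pseudo-labels like `G#2`); malformed rows and duplicated labels are hard
#' errors naming the offending line.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"sparky"`, `"csv"`.
#' @return A tibble: `residue`, `h_ppm`, `n_ppm` (possibly 0 rows).
#' @export
read_peaklist <- function(path, dialect = c("auto", "sparky", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "sparky"
  }
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  empty <- tibble::tibble(residue = character(), h_ppm = double(),
    n_ppm = double())
  if (length(lines_keep) == 0) return(empty)
  parse_row <- function(lineno, fields, h_col, n_col, label_col) {
    h <- suppressWarnings(as.numeric(fields[h_col]))
    n <- suppressWarnings(as.numeric(fields[n_col]))
    if (is.na(h) || is.na(n)) {
      rlang::abort(sprintf("%s: line %d: non-numeric chemical shift.", path, lineno),
        class = "quadbind_parse_error")
    }
    tibble::tibble(residue = fields[label_col], h_ppm = h, n_ppm = n)
  }
  if (dialect == "csv") {
    header <- strsplit(trimws(lines[lines_keep[1]]), ",")[[1]]
    if (!identical(trimws(header), c("residue", "h_ppm", "n_ppm"))) {
      rlang::abort(sprintf("%s: expected header 'residue,h_ppm,n_ppm'.", path),
        class = "quadbind_parse_error")
    }
    body <- lines_keep[-1]
    rows <- purrr::map(body, function(i) {
      fields <- trimws(strsplit(lines[i], ",")[[1]])
      if (length(fields) != 3) {
        rlang::abort(sprintf("%s: line %d: expected 3 fields, got %d.",
          path, i, length(fields)), class = "quadbind_parse_error")
      }
      parse_row(i, fields, h_col = 2, n_col = 3, label_col = 1)
    })
  } else {
    first <- lines_keep[1]
    if (grepl("Assignment", lines[first])) lines_keep <- lines_keep[-1]
    rows <- purrr::map(lines_keep, function(i) {
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(fields) < 3) {
        rlang::abort(sprintf("%s: line %d: expected 3 whitespace-separated fields.",
          path, i), class = "quadbind_parse_error")
      }
      # Sparky order: assignment, w1 (15N), w2 (1H)
      parse_row(i, fields, h_col = 3, n_col = 2, label_col = 1)
    })
  }
  out <- purrr::list_rbind(rows)
  dup <- out$residue[duplicated(out$residue)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("%s: duplicated residue label(s): %s.", path,
      paste(unique(dup), collapse = ", ")), class = "quadbind_parse_error")
  }
  out
}

#' Write a peak list
#'
#' Inverse of [read_peaklist()]; the CSV dialect round-trips bit-identically
#' through the reader.
#'
#' @param peaks Tibble with `residue`, `h_ppm`, `n_ppm`.
#' @param path Output path.
#' @param dialect `"csv"` or `"sparky"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, dialect = c("csv", "sparky")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    lines <- c("residue,h_ppm,n_ppm",
      sprintf("%s,%.6g,%.6g", peaks$residue, peaks$h_ppm, peaks$n_ppm))
  } else {
    lines <- c(sprintf("%10s %8s %8s", "Assignment", "w1", "w2"),
      sprintf("%10s %8.3f %8.3f", peaks$residue, peaks$n_ppm, peaks$h_ppm))
  }
  writeLines(lines, path)
  invisible(path)
}

# key: value metadata header lines beginning with '#'
.read_meta_header <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), ":")
  vals <- purrr::map(kv, function(x) trimws(x[2]))
  names(vals) <- purrr::map_chr(kv, function(x) trimws(x[1]))
  vals
}

#' Read an ITC run from CSV
#'
#' Dialect: `#`-prefixed metadata header (`cell_volume_ul`, `cell_conc_uM`,
#' `syringe_conc_uM`, `temperature_C`) followed by a CSV body with columns
#' `injection_ul,heat_ucal`.
#'
#' @param path File path.
#' @return An [itc_isotherm()].
#' @export
read_itc_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .read_meta_header(lines)
  need <- c("cell_volume_ul", "cell_conc_uM", "syringe_conc_uM", "temperature_C")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys) > 0) {
    rlang::abort(sprintf("%s: missing metadata: %s.", path,
      paste(missing_keys, collapse = ", ")), class = "quadbind_parse_error")
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("injection_ul", "heat_ucal") %in% names(body))) {
    rlang::abort(sprintf("%s: body must have columns injection_ul,heat_ucal.", path),
      class = "quadbind_parse_error")
  }
  sch <- itc_schedule(
    cell_conc_uM = as.numeric(meta$cell_conc_uM),
    syringe_conc_uM = as.numeric(meta$syringe_conc_uM),
    injection_ul = body$injection_ul,
    cell_volume_ul = as.numeric(meta$cell_volume_ul),
    temperature = as.numeric(meta$temperature_C) + 273.15
  )
  itc_isotherm(sch, body$heat_ucal)
}

#' Write an ITC run to CSV
#'
#' @param isotherm An [itc_isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(isotherm, path) {
  sch <- .get_schedule(isotherm)
  lines <- c(
    sprintf("# cell_volume_ul: %.6g", sch$cell_volume_ul),
    sprintf("# cell_conc_uM: %.6g", sch$cell_conc_uM),
    sprintf("# syringe_conc_uM: %.6g", sch$syringe_conc_uM),
    sprintf("# temperature_C: %.6g", sch$temperature - 273.15),
    "injection_ul,heat_ucal",
    sprintf("%.6g,%.10g", isotherm$injection_ul, isotherm$heat_ucal)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a CD scan or melting trace from CSV
#'
#' Two-column CSV with an optional `#`-prefixed metadata header; columns
#' either `wavelength_nm,ellipticity_mdeg` (scan) or
#' `temperature_C,ellipticity_mdeg` (melt). Metadata keys (`conc_M`,
#' `path_cm`, `n_residues`, `titrant_uM`) are attached as the `meta`
#' attribute when present.
#'
#' @param path File path.
#' @return A tibble with the file's columns (second column renamed
#'   `ellipticity`) and attribute `meta`.
#' @export
read_cd_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .read_meta_header(lines)
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (ncol(body) < 2) {
    rlang::abort(sprintf("%s: expected two columns.", path),
      class = "quadbind_parse_error")
  }
  names(body)[2] <- "ellipticity"
  out <- tibble::as_tibble(body)
  attr(out, "meta") <- purrr::map(meta, as.numeric)
  out
}

#' Assemble a thermodynamics report from fits
#'
#' Renders a table of equilibrium and thermodynamic parameters from one or
#' more one-site ITC fits (and optionally CSP fits, which contribute Kd and
#' dG only). dG and TdS are recomputed from the fitted Kd and dH, never
#' copied from elsewhere; flagged fits carry their flag through.
#'
#' @param fits A list of `itc_fit` and/or `csp_fit` objects.
#' @param labels Experiment labels, one per fit.
#' @param temperature Temperature (K) for the dG derivation (default
#'   298.15).
#' @return A tibble: `experiment`, `kd_uM`, `kd_se`, `dG`, `dH`, `dh_se`,
#'   `TdS`, `n`, `n_se`, `flag`.
#' @export
thermo_report <- function(fits, labels = NULL, temperature = 298.15) {
  if (inherits(fits, "itc_fit") || inherits(fits, "csp_fit")) fits <- list(fits)
  if (length(fits) == 0) {
    return(tibble::tibble(
      experiment = character(), kd_uM = double(), kd_se = double(),
      dG = double(), dH = double(), dh_se = double(), TdS = double(),
      n = double(), n_se = double(), flag = character()
    ))
  }
  if (is.null(labels)) labels <- paste0("fit", seq_along(fits))
  rows <- purrr::map2(fits, labels, function(f, lab) {
    if (inherits(f, "itc_fit")) {
      th <- thermo_from_kd_dh(f$kd_uM, f$dh, temperature, n = f$n)
      tibble::tibble(
        experiment = lab, kd_uM = f$kd_uM, kd_se = f$kd_se,
        dG = th$dG, dH = f$dh, dh_se = f$dh_se, TdS = th$TdS,
        n = f$n, n_se = f$n_se, flag = f$flag
      )
    } else if (inherits(f, "csp_fit")) {
      tibble::tibble(
        experiment = lab, kd_uM = f$kd_uM, kd_se = f$kd_se,
        dG = delta_g_from_kd(f$kd_uM, temperature), dH = NA_real_,
        dh_se = NA_real_, TdS = NA_real_, n = NA_real_, n_se = NA_real_,
        flag = f$flag
      )
    } else {
      rlang::abort("`fits` must contain itc_fit or csp_fit objects.",
        class = "quadbind_input_error")
    }
  })
  purrr::list_rbind(rows)
}

#' Write a thermodynamics report to CSV and JSON
#'
#' The CSV carries a header comment with the package version; the JSON is
#' the same rows as an array of objects.
#'
#' @param report Tibble from [thermo_report()].
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_thermo_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    version <- as.character(utils::packageVersion("quadbind"))
    con <- file(csv_path, "w")
    writeLines(sprintf("# quadbind %s thermodynamics report", version), con)
    utils::write.csv(report, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(c(csv_path, json_path))
}
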