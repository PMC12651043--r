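#' Read a shape-class counts table
#'
#' Counts CSV schema: header `donor_id, condition, shape_class, count`,
#' one row per donor x condition x class, UTF-8. Class names are
#' validated against the taxonomy; schema violations are reported with
#' the offending line number (header = line 1).
#'
#' @param path CSV file path.
#' @param taxonomy a [shape_taxonomy()] used for validation.
#' @return data.frame with the four schema columns (`count` integer).
#' @export
read_counts <- function(path, taxonomy = shape_taxonomy()) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor_id", "condition", "shape_class", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("counts file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[need]
  bad <- which(!df$shape_class %in% taxonomy$class)
  if (length(bad) > 0)
    stop(sprintf("unknown shape class '%s' in %s (line %d)",
                 df$shape_class[bad[1]], path, bad[1] + 1), call. = FALSE)
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad) > 0)
    stop(sprintf("invalid count '%s' in %s (line %d)",
                 df$count[bad[1]], path, bad[1] + 1), call. = FALSE)
  df$donor_id <- as.character(df$donor_id)
  df$count <- as.integer(df$count)
  df
}

#' Write a shape-class counts table
#'
#' Inverse of [read_counts()]: write-then-read reproduces the table
#' exactly.
#'
#' @param counts_df data.frame in the counts CSV schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts_df, path) {
  utils::write.csv(counts_df[c("donor_id", "condition", "shape_class", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an absorption spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-delimited `wavelength_nm absorbance`
#' files with an optional single header line. The wavelength grid must
#' be strictly increasing; a violation is reported with its line number.
#'
#' @param path file path.
#' @param condition,donor_id metadata attached to the spectrum.
#' @return An [absorption_spectrum()].
#' @export
read_spectrum <- function(path, condition = NA_character_,
                          donor_id = NA_character_) {
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spectrum file: ", path, call. = FALSE)
  parse_line <- function(x) {
    fields <- strsplit(trimws(x), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_line(lines[1])
  skip <- if (any(is.na(first))) 1L else 0L  # header line
  vals <- lapply(lines[(1 + skip):length(lines)], parse_line)
  bad <- which(vapply(vals, function(v) length(v) < 2 || any(is.na(v[1:2])), TRUE))
  if (length(bad) > 0)
    stop(sprintf("malformed spectrum line %d in %s: '%s'",
                 bad[1] + skip, path, lines[bad[1] + skip]), call. = FALSE)
  wl <- vapply(vals, `[`, numeric(1), 1)
  ab <- vapply(vals, `[`, numeric(1), 2)
  nonmono <- which(diff(wl) <= 0)
  if (length(nonmono) > 0)
    stop(sprintf("wavelengths not strictly increasing at line %d of %s (%g nm)",
                 nonmono[1] + 1 + skip, path, wl[nonmono[1] + 1]), call. = FALSE)
  absorption_spectrum(wl, ab, condition = condition, donor_id = donor_id)
}

#' Write an absorption spectrum as two-column text
#'
#' @param s an [absorption_spectrum()].
#' @param path output path.
#' @param digits significant digits written (default 10; round trip is
#'   then exact to float round-off).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, digits = 10) {
  lines <- c("wavelength_nm\tabsorbance",
             sprintf("%.*g\t%.*g", digits, s$wavelength, digits, s$absorbance))
  writeLines(lines, path)
  invisible(path)
}

# --- pipeline configuration ----------------------------------------------

pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    counts_file = NULL,
    simulate_counts = list(conditions = reference_cytoarchitectonics()$conditions,
                           n_donors = 30, cells_per_donor = 1000,
                           overdispersion = 1500),
    spectra_files = NULL,
    simulate_spectra = NULL,
    normalize_od = NULL,
    band_windows = default_band_windows(),
    rounding = list(TI = 1, RTI = 1, IRTI = 2, percent = 1),
    taxonomy_extra = NULL,
    control_condition = "control"
  )
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML mapping; unknown top-level keys are
#' rejected with a clear message, and defaults are filled in for any
#' key left out. A config of `NULL` (or an empty file) yields the full
#' default configuration: simulate 30 donors x 1000 cells for the five
#' reference conditions, alpha 0.05, default band windows and rounding.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `pipeline_config` list.
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  as_pipeline_config(user)
}

#' @rdname read_config
#' @param config named list of overrides (same keys as the YAML form).
#' @export
as_pipeline_config <- function(config = list()) {
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(is.numeric(cfg$alpha), cfg$alpha > 0, cfg$alpha < 1)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$simulate_spectra)) {
    for (lab in names(cfg$simulate_spectra$conditions)) {
      v <- cfg$simulate_spectra$conditions[[lab]]
      if (length(v) != 3 || any(!is.finite(as.numeric(v))))
        stop("simulate_spectra condition '", lab,
             "' must give a (HbO2, Hb, MtHb) concentration triple", call. = FALSE)
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Serialize a pipeline configuration back to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
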