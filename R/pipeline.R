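#' Run the full analysis pipeline
#'
#' Deterministic end-to-end run: (simulate or read) shape counts ->
#' per-donor profiles and indices -> per-condition summaries and
#' Student's t-tests against the control -> (optionally) spectra ->
#' ligand-form speciation, band metrics and percent changes. Inferred
#' reporting conventions (RTI = RD/D, IRTI = ID/D) are logged once per
#' run to standard error. The same configuration and seed always give an
#' identical report.
#'
#' @param config a `pipeline_config` from [read_config()] /
#'   [as_pipeline_config()], or a plain list of overrides.
#' @param verbose log progress and fired defaults to stderr.
#' @return Object of class `analysis_report`: list with `profiles`
#'   (per-donor data.frame), `index_summary` (per-condition mean/SEM and
#'   rounded values for D, RD, ID, TI, RTI, IRTI), `t_tests`
#'   (vs control), `speciation` (per condition, if spectra were given),
#'   `band_metrics`, `percent_changes`, and the `config` used.
#' @examples
#' rep <- run_pipeline(list(simulate_counts = list(
#'   conditions = c("control", "MC_24h"), n_donors = 5,
#'   cells_per_donor = 1000, overdispersion = 1500), seed = 7),
#'   verbose = FALSE)
#' rep$index_summary[rep$index_summary$metric == "TI", ]
#' @export
run_pipeline <- function(config = NULL, verbose = TRUE) {
  if (is.null(config)) config <- as_pipeline_config()
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  log_msg <- function(...) if (verbose) message(...)
  log_msg("inferred convention: RTI = RD/D, IRTI = ID/D (validated against ",
          "the reference index table)")

  taxonomy <- shape_taxonomy(config$taxonomy_extra)

  # --- counts: read or simulate ---
  if (!is.null(config$counts_file)) {
    log_msg("reading counts from ", config$counts_file)
    counts <- read_counts(config$counts_file, taxonomy)
  } else {
    sc <- config$simulate_counts
    log_msg(sprintf("simulating counts: %d donors x %d cells, %d conditions",
                    sc$n_donors, sc$cells_per_donor, length(sc$conditions)))
    counts <- do.call(rbind, lapply(seq_along(sc$conditions), function(i) {
      cond <- sc$conditions[[i]]
      simulate_counts(reference_probabilities(cond, quiet = TRUE),
                      n_donors = sc$n_donors,
                      cells_per_donor = sc$cells_per_donor,
                      condition = cond,
                      overdispersion = sc$overdispersion,
                      seed = config$seed + i)
    }))
  }

  # --- per-donor profiles, per-condition summaries ---
  profiles <- profile_table(counts, taxonomy)
  conditions <- unique(profiles$condition)
  metrics <- c("D", "RD", "ID", "TI", "RTI", "IRTI")
  dec <- config$rounding
  decimals_of <- c(D = dec$percent, RD = dec$percent, ID = dec$percent,
                   TI = dec$TI, RTI = dec$RTI, IRTI = dec$IRTI)
  index_summary <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- profiles[profiles$condition == cond, ]
    do.call(rbind, lapply(metrics, function(m) {
      gs <- summarize_group(sub[[m]], label = paste(cond, m))
      data.frame(condition = cond, metric = m, n = gs$n, mean = gs$mean,
                 sd = gs$sd, sem = gs$sem,
                 rounded = round_reported(gs$mean, decimals_of[[m]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(index_summary) <- NULL

  # --- t-tests vs control ---
  ctrl <- config$control_condition
  t_tests <- NULL
  if (ctrl %in% conditions && length(conditions) > 1) {
    others <- setdiff(conditions, ctrl)
    t_tests <- do.call(rbind, lapply(others, function(cond) {
      do.call(rbind, lapply(metrics, function(m) {
        a <- profiles[[m]][profiles$condition == ctrl]
        b <- profiles[[m]][profiles$condition == cond]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        tt <- student_t(a, b, alpha = config$alpha)
        data.frame(condition = cond, metric = m, t = tt$t, df = tt$df,
                   p = tt$p, significant = tt$significant,
                   stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(t_tests)) {
      rownames(t_tests) <- NULL
      log_msg(sprintf("performed %d t-tests at alpha = %g (no multiplicity ",
                      nrow(t_tests), config$alpha), "correction applied)")
    }
  }

  # --- spectra: read or simulate, then speciate + band metrics ---
  model <- hb_deconvolution_model()
  spectra <- list()
  if (!is.null(config$spectra_files)) {
    for (lab in names(config$spectra_files))
      spectra[[lab]] <- read_spectrum(config$spectra_files[[lab]],
                                      condition = lab)
  } else if (!is.null(config$simulate_spectra)) {
    ss <- config$simulate_spectra
    noise_sd <- if (is.null(ss$noise_sd)) 0.001 else ss$noise_sd
    labs <- names(ss$conditions)
    for (i in seq_along(labs)) {
      spectra[[labs[i]]] <- simulate_spectrum(
        as.numeric(ss$conditions[[labs[i]]]), model = model,
        noise_sd = noise_sd, seed = config$seed + 1000 + i,
        condition = labs[i])
    }
    log_msg(sprintf("simulated %d spectra (photometric noise sd %g Abs)",
                    length(labs), noise_sd))
  }

  speciation <- band_metrics <- percent_changes <- NULL
  if (length(spectra) > 0) {
    if (!is.null(config$normalize_od)) {
      log_msg("normalizing spectra to OD ", config$normalize_od,
              " at the Soret-window maximum (default reference policy)")
      spectra <- lapply(spectra, normalize_to_od, target = config$normalize_od)
    }
    speciation <- do.call(rbind, lapply(names(spectra), function(lab) {
      sp <- speciate(anchors_from_spectrum(spectra[[lab]], model), model)
      data.frame(condition = lab,
                 species = names(sp$concentrations),
                 concentration = unname(sp$concentrations),
                 fraction = unname(sp$fractions),
                 negative_flag = sp$negative,
                 stringsAsFactors = FALSE)
    }))
    band_metrics <- do.call(rbind, lapply(names(spectra), function(lab) {
      bm <- extract_band_metrics(spectra[[lab]], config$band_windows)
      cbind(condition = lab, bm)
    }))
    rownames(band_metrics) <- NULL
    if (ctrl %in% band_metrics$condition) {
      ctrl_bm <- band_metrics[band_metrics$condition == ctrl, ]
      others <- setdiff(unique(band_metrics$condition), ctrl)
      percent_changes <- do.call(rbind, lapply(others, function(lab) {
        trt <- band_metrics[band_metrics$condition == lab, ]
        common <- intersect(trt$band, ctrl_bm$band)
        data.frame(
          condition = lab, band = common,
          pct_decrease = percent_change(
            trt$peak_abs[match(common, trt$band)],
            ctrl_bm$peak_abs[match(common, ctrl_bm$band)]),
          stringsAsFactors = FALSE)
      }))
    }
  }

  structure(
    list(profiles = profiles, index_summary = index_summary,
         t_tests = t_tests, speciation = speciation,
         band_metrics = band_metrics, percent_changes = percent_changes,
         config = config),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", length(unique(x$profiles$condition)),
      "conditions,", length(unique(x$profiles$donor_id)), "donors\n")
  wide <- stats::reshape(
    x$index_summary[c("condition", "metric", "rounded")],
    idvar = "metric", timevar = "condition", direction = "wide")
  names(wide) <- sub("^rounded\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (!is.null(x$t_tests))
    cat(sum(x$t_tests$significant), "of", nrow(x$t_tests),
        "t-tests significant at alpha =", x$config$alpha, "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable TSV (`<stem>.tsv`: columns condition,
#' metric, n, mean, sem, rounded -- unrounded means always retained), a
#' t-test TSV (`<stem>_ttests.tsv`), speciation and band TSVs when
#' present, and a human-readable text block (`<stem>.txt`).
#'
#' @param report an `analysis_report`.
#' @param stem output path stem (directory must exist).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, stem) {
  files <- character(0)
  wr <- function(df, suffix) {
    f <- paste0(stem, suffix)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wr(report$index_summary, ".tsv")
  if (!is.null(report$t_tests)) wr(report$t_tests, "_ttests.tsv")
  if (!is.null(report$speciation)) wr(report$speciation, "_speciation.tsv")
  if (!is.null(report$band_metrics)) wr(report$band_metrics, "_bands.tsv")
  if (!is.null(report$percent_changes)) wr(report$percent_changes, "_pctchange.tsv")
  txt <- paste0(stem, ".txt")
  writeLines(utils::capture.output(print(report)), txt)
  files <- c(files, txt)
  invisible(files)
}
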