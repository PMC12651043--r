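#' Reference cytoarchitectonics of minocycline-modified erythrocytes
#'
#' Published per-condition mean percentages of erythrocyte shape classes
#' (30 healthy donors; SEM counting) for five conditions: untreated
#' control, 1 h and 24 h incubation with minocycline (MC), and each
#' incubation followed by washing with 1% bovine serum albumin (BSA).
#' These are the calibration surface for the synthetic count generator
#' and the fixture for index-reproduction tests.
#'
#' Category rows (`D`, `RD`, `ID`) are per-donor means and therefore can
#' differ from sums of the printed per-class means by up to 0.2
#' percentage points; within any one donor RD + ID = 100 exactly.
#'
#' @return A list with components:
#'   \describe{
#'     \item{`class_pct`}{data.frame, one row per shape class, one column
#'       per condition, mean percentages.}
#'     \item{`category`}{data.frame with rows `D`, `RD`, `ID` (printed
#'       category means, percent).}
#'     \item{`indices`}{data.frame with rows `TI`, `RTI`, `IRTI`
#'       (printed index means, reporting precision 1/1/2 decimals).}
#'     \item{`conditions`}{character vector of condition labels.}
#'   }
#' @export
reference_cytoarchitectonics <- function() {
  conditions <- c("control", "MC_1h", "MC_1h_BSA", "MC_24h", "MC_24h_BSA")
  class_pct <- data.frame(
    shape_class = c("discocyte", "echinocyte", "discocyte_with_ridge",
                    "deflated_ball", "dome_shaped", "spherocyte",
                    "stomatocyte", "degenerative", "spherocyte_with_spikes"),
    control    = c(91.1, 3.5, 3.1, 0.2, 1.2, 0.0, 0.0, 0.5, 0.4),
    MC_1h      = c(85.2, 5.2, 6.1, 1.1, 1.2, 0.06, 0.02, 0.6, 0.5),
    MC_1h_BSA  = c(88.7, 1.5, 6.0, 1.2, 1.8, 0.09, 0.01, 0.6, 0.1),
    MC_24h     = c(81.4, 7.4, 6.2, 1.6, 1.3, 0.5, 0.1, 0.7, 0.7),
    MC_24h_BSA = c(85.9, 4.0, 5.6, 1.6, 1.2, 0.5, 0.2, 0.7, 0.2),
    stringsAsFactors = FALSE
  )
  category <- data.frame(
    row.names  = c("D", "RD", "ID"),
    control    = c(91.1, 97.6, 2.4),
    MC_1h      = c(85.2, 96.4, 3.5),
    MC_1h_BSA  = c(88.7, 96.2, 3.7),
    MC_24h     = c(81.4, 95.0, 5.1),
    MC_24h_BSA = c(85.9, 95.4, 4.5)
  )
  indices <- data.frame(
    row.names  = c("TI", "RTI", "IRTI"),
    control    = c(1.1, 1.1, 0.03),
    MC_1h      = c(1.2, 1.1, 0.04),
    MC_1h_BSA  = c(1.1, 1.1, 0.04),
    MC_24h     = c(1.2, 1.2, 0.06),
    MC_24h_BSA = c(1.2, 1.1, 0.05)
  )
  list(class_pct = class_pct, category = category, indices = indices,
       conditions = conditions)
}

#' Shape-class probability vector for a reference condition
#'
#' Converts a reference condition's class percentages into a probability
#' vector for [simulate_counts()]. Printed columns sum to 99.9--100.1
#' because of per-class rounding; the vector is renormalized to sum to 1
#' (a message notes the adjustment when it exceeds 1e-9).
#'
#' @param condition one of the reference condition labels.
#' @param quiet suppress the renormalization message.
#' @return Named probability vector over shape classes summing to 1.
#' @export
reference_probabilities <- function(condition = "control", quiet = FALSE) {
  ref <- reference_cytoarchitectonics()
  if (!condition %in% ref$conditions)
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(ref$conditions, collapse = ", "), call. = FALSE)
  p <- setNames(ref$class_pct[[condition]] / 100, ref$class_pct$shape_class)
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    if (!quiet)
      message(sprintf(
        "condition '%s': printed percentages sum to %.2f; renormalizing to 100",
        condition, 100 * s))
    p <- p / s
  }
  p
}

#' Reference counts table at a fixed cells-per-donor resolution
#'
#' Deterministic single-donor counts for each reference condition,
#' obtained by scaling the condition's class percentages to
#' `cells_per_donor` cells (largest-remainder apportionment so counts are
#' integers summing exactly to `cells_per_donor`). This is the packaged
#' fixture that flows through the full pipeline in the integration tests.
#'
#' @param cells_per_donor integer, default 10000 (so that 0.01% classes
#'   keep at least one cell where the reference lists 0.01).
#' @return data.frame in the counts CSV schema (`donor_id`, `condition`,
#'   `shape_class`, `count`).
#' @export
reference_counts_fixture <- function(cells_per_donor = 10000) {
  ref <- reference_cytoarchitectonics()
  rows <- lapply(ref$conditions, function(cond) {
    p <- reference_probabilities(cond, quiet = TRUE)
    exact <- p * cells_per_donor
    cnt <- floor(exact)
    short <- cells_per_donor - sum(cnt)
    if (short > 0) {
      ord <- order(exact - cnt, decreasing = TRUE)
      cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
    }
    data.frame(donor_id = "ref", condition = cond,
               shape_class = names(p), count = as.integer(cnt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
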