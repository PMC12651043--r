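#' Percentage profile of a shape-count vector
#'
#' Turns raw per-donor cell counts over shape classes into the percentage
#' profile used for transformation indices: per-class percentages `pct`,
#' percent discocytes `D`, percent reversibly deformed `RD` (which
#' includes discocytes) and percent irreversibly deformed `ID`.
#' `RD + ID = 100` exactly for any valid count vector, before any
#' reporting rounding.
#'
#' @param counts named numeric vector of non-negative cell counts; names
#'   are shape classes resolvable in `taxonomy`.
#' @param taxonomy a [shape_taxonomy()].
#' @param condition optional condition label carried into the result.
#' @param donor_id optional donor identifier carried into the result.
#' @return An object of class `morphology_profile`: a list with `pct`
#'   (named percentages), `D`, `RD`, `ID`, `n_cells`, `condition`,
#'   `donor_id`.
#' @examples
#' p <- aggregate_profile(c(discocyte = 911, echinocyte = 35,
#'                          discocyte_with_ridge = 31, dome_shaped = 12,
#'                          deflated_ball = 2, degenerative = 5,
#'                          spherocyte_with_spikes = 4))
#' p$D   # 91.1
#' p$RD  # 97.7
#' @export
aggregate_profile <- function(counts, taxonomy = shape_taxonomy(),
                              condition = NA_character_,
                              donor_id = NA_character_) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a fully named vector of shape-class counts", call. = FALSE)
  check_classes(names(counts), taxonomy)
  if (any(counts < 0)) stop("negative cell count", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("zero total cell count", call. = FALSE)

  pct <- 100 * counts / total
  cat_of <- taxonomy$category[match(names(counts), taxonomy$class)]
  D  <- sum(pct[names(counts) == "discocyte"])
  RD <- sum(pct[cat_of == "RD"])
  ID <- sum(pct[cat_of == "ID"])
  structure(
    list(pct = pct, D = D, RD = RD, ID = ID, n_cells = total,
         condition = condition, donor_id = donor_id),
    class = "morphology_profile"
  )
}

#' Construct a morphology profile directly from category percentages
#'
#' Used when only the summary percentages (as printed in a report table)
#' are available rather than raw counts.
#'
#' @param D percent discocytes.
#' @param RD percent reversibly deformed (must include `D`).
#' @param ID percent irreversibly deformed.
#' @param condition optional condition label.
#' @return A `morphology_profile` with empty per-class `pct`.
#' @export
profile_from_percent <- function(D, RD, ID, condition = NA_character_) {
  stopifnot(is.finite(D), is.finite(RD), is.finite(ID))
  if (D > RD + 1e-9) stop("D cannot exceed RD (discocytes are counted in RD)",
                          call. = FALSE)
  if (ID < 0 || ID > 100) stop("ID must lie in [0, 100]", call. = FALSE)
  structure(
    list(pct = numeric(0), D = D, RD = RD, ID = ID, n_cells = NA_real_,
         condition = condition, donor_id = NA_character_),
    class = "morphology_profile"
  )
}

#' Transformation indices from a morphology profile
#'
#' The transformation index is the ratio of all cells to discocytes,
#' `TI = (RD + ID)/D`; its reversible and irreversible components are
#' `RTI = RD/D` and `IRTI = ID/D`, so `TI = RTI + IRTI` identically.
#' `TI = 1` when every cell is a discocyte and grows as discocytes are
#' lost. Unrounded values are always returned; reported values use the
#' conventional precision (1 decimal for TI and RTI, 2 for IRTI) via
#' [round_reported()].
#'
#' @param profile a `morphology_profile` (or any list with `D`, `RD`, `ID`).
#' @param decimals named vector of reporting decimals,
#'   default `c(TI = 1, RTI = 1, IRTI = 2)`.
#' @return An object of class `index_set`: list with unrounded `TI`,
#'   `RTI`, `IRTI`, a `reported` named vector (rounded), and the
#'   `decimals` used.
#' @examples
#' compute_indices(profile_from_percent(D = 91.1, RD = 97.6, ID = 2.4))
#' @export
compute_indices <- function(profile, decimals = c(TI = 1, RTI = 1, IRTI = 2)) {
  D <- profile$D; RD <- profile$RD; ID <- profile$ID
  if (!is.finite(D) || D <= 0)
    stop("transformation indices are undefined when D = 0 (no discocytes)",
         call. = FALSE)
  TI <- (RD + ID) / D
  RTI <- RD / D
  IRTI <- ID / D
  structure(
    list(TI = TI, RTI = RTI, IRTI = IRTI,
         reported = c(TI = round_reported(TI, decimals[["TI"]]),
                      RTI = round_reported(RTI, decimals[["RTI"]]),
                      IRTI = round_reported(IRTI, decimals[["IRTI"]])),
         decimals = decimals,
         condition = profile$condition),
    class = "index_set"
  )
}

#' Round half away from zero at a given number of decimals
#'
#' Report tables conventionally round half-way cases away from zero
#' (2.35 -> 2.4), unlike R's banker's rounding. The scaled value is first
#' snapped to 12 significant digits so that binary representation error
#' cannot flip a half-way case.
#'
#' @param value numeric vector.
#' @param decimals non-negative integer number of decimals.
#' @return `value` rounded half-away-from-zero.
#' @examples
#' round_reported(1.1725, 1)  # 1.2
#' round_reported(0.0263, 2)  # 0.03
#' @export
round_reported <- function(value, decimals) {
  stopifnot(decimals >= 0, decimals == as.integer(decimals))
  scaled <- signif(abs(value) * 10^decimals, 12)
  sign(value) * floor(scaled + 0.5) / 10^decimals
}

#' @export
print.morphology_profile <- function(x, ...) {
  cat(sprintf("Morphology profile%s%s\n",
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
              if (!is.na(x$donor_id)) paste0(" donor ", x$donor_id) else ""))
  cat(sprintf("  D = %.2f%%  RD = %.2f%%  ID = %.2f%%  (n = %s cells)\n",
              x$D, x$RD, x$ID, format(x$n_cells)))
  invisible(x)
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("TI = %.4f (reported %s)  RTI = %.4f (%s)  IRTI = %.4f (%s)\n",
              x$TI, format(x$reported[["TI"]]),
              x$RTI, format(x$reported[["RTI"]]),
              x$IRTI, format(x$reported[["IRTI"]])))
  invisible(x)
}

#' Per-donor profiles and indices for a counts table
#'
#' Applies [aggregate_profile()] and [compute_indices()] to every
#' donor-by-condition cell of a long counts table (exact per-donor
#' profiles, averaged afterwards: mean of ratios, not ratio of means).
#'
#' @param counts_df data.frame with columns `donor_id`, `condition`,
#'   `shape_class`, `count` (the counts CSV schema).
#' @param taxonomy a [shape_taxonomy()].
#' @return data.frame with one row per donor x condition and columns
#'   `donor_id`, `condition`, `D`, `RD`, `ID`, `TI`, `RTI`, `IRTI`.
#' @export
profile_table <- function(counts_df, taxonomy = shape_taxonomy()) {
  need <- c("donor_id", "condition", "shape_class", "count")
  missing_cols <- setdiff(need, names(counts_df))
  if (length(missing_cols) > 0)
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  check_classes(unique(counts_df$shape_class), taxonomy)
  key <- interaction(counts_df$donor_id, counts_df$condition, drop = TRUE)
  rows <- lapply(split(counts_df, key), function(d) {
    cnt <- tapply(d$count, d$shape_class, sum)
    p <- aggregate_profile(setNames(as.numeric(cnt), names(cnt)), taxonomy,
                           condition = d$condition[1], donor_id = as.character(d$donor_id[1]))
    ix <- compute_indices(p)
    data.frame(donor_id = as.character(d$donor_id[1]), condition = d$condition[1],
               D = p$D, RD = p$RD, ID = p$ID,
               TI = ix$TI, RTI = ix$RTI, IRTI = ix$IRTI,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
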