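#' Shape-class taxonomy for erythrocyte cytoarchitectonics
#'
#' Scanning electron microscopy classifies erythrocytes into named shape
#' classes, each belonging to one of two categories: reversibly deformed
#' (RD) or irreversibly deformed (ID). The discocyte -- the normal
#' biconcave disk -- is counted inside RD and is additionally the
#' denominator of all transformation indices.
#'
#' The default taxonomy places stomatocytes in the ID category: category
#' totals of observed count tables are only internally consistent under
#' that assignment. The taxonomy is a plain data frame, so alternative
#' assignments (e.g. stomatocyte in RD) can be expressed by editing it.
#'
#' @param extra optional data frame with columns `class` and `category`
#'   (`"RD"` or `"ID"`) appended to the default classes, e.g. to register
#'   a new shape class.
#' @return A data.frame of class `shape_taxonomy` with columns `class`,
#'   `category` and `is_discocyte`.
#' @examples
#' tax <- shape_taxonomy()
#' subset(tax, category == "ID")$class
#' @export
shape_taxonomy <- function(extra = NULL) {
  rd <- c("discocyte", "echinocyte", "discocyte_with_ridge", "mulberry")
  id <- c("deflated_ball", "dome_shaped", "spherocyte", "stomatocyte",
          "degenerative", "spherocyte_with_spikes")
  tax <- data.frame(
    class = c(rd, id),
    category = c(rep("RD", length(rd)), rep("ID", length(id))),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("class", "category") %in% names(extra)))
    if (!all(extra$category %in% c("RD", "ID")))
      stop("taxonomy categories must be 'RD' or 'ID'", call. = FALSE)
    tax <- rbind(tax, extra[, c("class", "category")])
  }
  if (anyDuplicated(tax$class))
    stop("duplicate shape class in taxonomy: ",
         paste(unique(tax$class[duplicated(tax$class)]), collapse = ", "),
         call. = FALSE)
  tax$is_discocyte <- tax$class == "discocyte"
  class(tax) <- c("shape_taxonomy", "data.frame")
  tax
}

# resolve class names against a taxonomy; unknown names are a hard error
check_classes <- function(classes, taxonomy) {
  unknown <- setdiff(classes, taxonomy$class)
  if (length(unknown) > 0)
    stop("unknown shape class: ", paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
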