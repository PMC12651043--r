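#' Per-group summary: n, mean, sd, SEM
#'
#' Produces the `mean ± SEM` cells of a condition summary table. The sd
#' uses the n-1 denominator; for a single observation the sd and SEM are
#' reported as 0 with a `degenerate` flag.
#'
#' @param values numeric vector (at least one value).
#' @param label group label.
#' @return Object of class `group_summary`: list with `n`, `mean`, `sd`,
#'   `sem`, `label`, `degenerate`.
#' @examples
#' summarize_group(c(1, 2, 3))  # mean 2, sem 0.577
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("cannot summarize an empty group", call. = FALSE)
  s <- if (n > 1) stats::sd(values) else 0
  structure(
    list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n),
         label = label, degenerate = n == 1),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g ± %.4g (SEM), n = %d%s\n",
              if (is.na(x$label)) "group" else x$label, x$mean, x$sem, x$n,
              if (x$degenerate) " [single observation]" else ""))
  invisible(x)
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance Student's t-test (the default), with Welch
#' and donor-paired variants available. Significance is declared at
#' `p <= alpha` (default alpha 0.05). If both groups are constant and
#' equal -- zero variance, zero difference -- the test is reported as
#' t = 0, p = 1 rather than an error.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param alpha significance level, default 0.05.
#' @param welch use the Welch unequal-variance test instead of pooled.
#' @param paired donor-paired test (requires equal lengths).
#' @return Object of class `t_test_result`: list with `t`, `df`, `p`,
#'   `significant`, `alpha`, `method`.
#' @examples
#' student_t(c(1, 2, 3, 4), c(2, 3, 4, 5))  # t = -1.095, df = 6
#' @export
student_t <- function(group_a, group_b, alpha = 0.05, welch = FALSE,
                      paired = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group sizes", call. = FALSE)

  constant <- stats::var(group_a) == 0 && stats::var(group_b) == 0
  if (constant && isTRUE(all.equal(mean(group_a), mean(group_b)))) {
    df <- if (paired) length(group_a) - 1 else length(group_a) + length(group_b) - 2
    res <- list(t = 0, df = df, p = 1)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = !welch, paired = paired)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(
    c(res, list(significant = res$p <= alpha, alpha = alpha,
                method = if (paired) "paired" else if (welch) "welch" else "pooled")),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Student's t (%s): t = %.4f, df = %.4g, p = %.4g%s\n",
              x$method, x$t, x$df, x$p,
              if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha)
              else ""))
  invisible(x)
}
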