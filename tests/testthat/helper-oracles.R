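# Independent oracles, written before and kept independent of the
# implementation paths they check.

# 3x3 matrix inverse via Cramer's rule / cofactor expansion.
cramer_inverse_3x3 <- function(M) {
  cof <- function(i, j) {
    minor <- M[-i, -j, drop = FALSE]
    (-1)^(i + j) * (minor[1, 1] * minor[2, 2] - minor[1, 2] * minor[2, 1])
  }
  # determinant by explicit first-row expansion
  d <- M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
       M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
       M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  adj <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) adj[j, i] <- cof(i, j)
  adj / d
}

# textbook pooled-variance two-sample t statistic
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# random valid count vector over the default taxonomy classes
random_counts <- function(n_classes = 6, max_count = 500) {
  tax <- shape_taxonomy()
  classes <- sample(tax$class, n_classes)
  if (!"discocyte" %in% classes) classes[1] <- "discocyte"
  cnt <- sample.int(max_count, length(classes), replace = TRUE)
  setNames(cnt, classes)
}
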