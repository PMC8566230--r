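#' Multiple-testing adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()]: Benjamini-Hochberg
#' step-up q-values (`"bh_fdr"`) or Bonferroni (`min(1, p*m)`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bh_fdr"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh_fdr", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = switch(method, bh_fdr = "BH", bonferroni = "bonferroni"))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions, ~0 for independent ones. Used to compare recovered cluster
#' labels with generator ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# fast two-sided Welch t-test p-values, one gene per row, x vs y matrices
row_welch_t <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant in both groups: no evidence
  list(t = tstat, p = p)
}
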