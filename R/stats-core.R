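# Shared statistical primitives. Everything downstream (DEG calling, bias,
# ELD, enrichment) is built on the four operations in this file.

# Relative tolerance used wherever two means are compared for exact equality
# (degenerate-variance t-test branch, exact-mean truth oracle). Sums of
# template means such as 0.7*m + 0.3*m differ from 1.0*m by floating-point
# rounding; a strict `==` would misclassify noise-free data.
NEAR_TOL <- 1e-9

near_equal <- function(a, b) {
  abs(a - b) <= NEAR_TOL * pmax(abs(a), abs(b), 1)
}

#' Two-sample t-test with a ternary outcome
#'
#' Student's (pooled-variance) two-sample t-test returning a three-way call
#' for the first sample relative to the second: `"LT"`, `"EQ"` or `"GT"`.
#' The call is `"EQ"` exactly when `p > alpha`; otherwise the sign of
#' `mean(x) - mean(y)` decides. This is the comparison atom used throughout
#' the homoeolog bias and expression-level-dominance decision tables, where
#' homoeolog and pair-total expression levels are compared at P <= 0.05.
#'
#' When the pooled variance is zero (all replicates identical within each
#' sample) the test degenerates; by convention `p = 1` when the two means are
#' equal (to within a relative tolerance of 1e-9) and `p = 0` otherwise, so
#' noise-free data classify exactly.
#'
#' @param x,y Numeric replicate vectors, each of length >= 2.
#' @param alpha Significance level for the ternary call (default 0.05).
#' @param var_equal If `TRUE` (default) use the pooled-variance Student
#'   statistic; if `FALSE` use the Welch statistic.
#' @return A one-row tibble with columns `p`, `direction` (`"LT"`, `"EQ"`,
#'   `"GT"`), `mean_x` and `mean_y`.
#' @examples
#' ternary_t_test(c(1, 2, 3), c(1, 2, 3))       # EQ, p = 1
#' ternary_t_test(c(10, 10, 10), c(20, 20, 20)) # LT, p = 0
#' @export
ternary_t_test <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort("`x` and `y` must be numeric replicate vectors.")
  }
  row_t_test(matrix(x, nrow = 1), matrix(y, nrow = 1),
             alpha = alpha, var_equal = var_equal)
}

# Vectorised work-horse: one t-test per row of X against the same row of Y.
# X, Y: matrices with one column per replicate.
row_t_test <- function(X, Y, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  n1 <- ncol(X)
  n2 <- ncol(Y)
  if (n1 < 2 || n2 < 2) {
    abort("each sample needs at least 2 replicates.")
  }
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    abort("replicate values must be finite.")
  }
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (n1 - 1)
  vy <- rowSums((Y - my)^2) / (n2 - 1)
  if (var_equal) {
    df <- rep(n1 + n2 - 2, nrow(X))
    se <- sqrt((((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)) *
                 (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(vx / n1 + vy / n2)
    df <- (vx / n1 + vy / n2)^2 /
      ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  }
  # A standard error at the level of floating-point rounding of the means is
  # numerical noise, not replicate variability; such rows fall back to the
  # degenerate-variance convention (p = 1 if means equal, p = 0 otherwise).
  degen <- se <= NEAR_TOL * pmax(abs(mx), abs(my), 1)
  tstat <- (mx - my) / se
  tstat[degen] <- 0
  df[degen] <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df = df)
  p[degen] <- ifelse(near_equal(mx[degen], my[degen]), 1, 0)
  direction <- ifelse(p > alpha, "EQ", ifelse(mx > my, "GT", "LT"))
  tibble(p = unname(p), direction = unname(direction),
         mean_x = unname(mx), mean_y = unname(my))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment of a p-value vector; input order is preserved.
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`,
#' the field-default procedure behind every "FDR <= cutoff" rule in this
#' package (DEG calling at FDR <= 0.05, enrichment at FDR <= 0.001).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric and lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Log2 fold change between two mean expression values
#'
#' `log2((mean_x + pseudocount) / (mean_y + pseudocount))`. The pseudocount
#' (default 1 FPKM) keeps zero-expression genes finite.
#'
#' @param mean_x,mean_y Non-negative mean expression values (vectorised).
#' @param pseudocount Positive stabilising constant (default 1).
#' @return Fold change in bits (vectorised).
#' @examples
#' log2_fold_change(4, 1) # log2(5/2)
#' @export
log2_fold_change <- function(mean_x, mean_y, pseudocount = 1) {
  if (any(mean_x < 0) || any(mean_y < 0)) {
    abort("mean expression values must be non-negative.")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  log2((mean_x + pseudocount) / (mean_y + pseudocount))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes in a study set of size `n` from a background
#' of `N` genes of which `K` carry the annotation. This one-sided test
#' (Fisher's exact upper tail) is the enrichment statistic used by
#' [enrich()].
#'
#' @param k Annotated genes observed in the study set.
#' @param n Study-set size.
#' @param K Annotated genes in the background.
#' @param N Background size.
#' @return Upper-tail p-value (vectorised over `k`, `n`, `K`, `N`).
#' @examples
#' hypergeom_tail(4, 5, 5, 20) # 76/15504
#' @export
hypergeom_tail <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0
  if (any(bad)) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= min(n, K) and n, K <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
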