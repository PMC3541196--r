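#' Per-gene two-sample t-statistics
#'
#' Computes, for every gene, the classical two-sample t-statistic with
#' the numerator oriented as mean(tumor) minus mean(normal), so positive
#' values mean tumor upregulation. The default is the pooled-variance
#' (Student) form; Welch's unequal-variance form is available as a
#' switch. A gene whose pooled variance is zero scores t = 0 when the
#' group means are equal; when the means differ the t-statistic is
#' unbounded, and such genes are flagged (with a warning) by `+/-Inf` so
#' that [rank_scores()] can place them at the extreme rank in the
#' direction of the mean difference instead of propagating infinities.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels 0/1 phenotype vector aligned to the columns (0 = normal,
#'   1 = tumor).
#' @param var_equal Use the pooled-variance t (default TRUE); FALSE gives
#'   Welch.
#' @return Numeric vector of t-statistics named by gene.
#' @export
gene_t_statistics <- function(expr, labels, var_equal = TRUE) {
  validate_labels(labels, expr)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  if (length(idx1) < 2L || length(idx0) < 2L) {
    stop("each class needs at least 2 samples")
  }
  t <- .t_stat_rows(expr, idx1, idx0, var_equal = var_equal)
  if (any(is.infinite(t))) {
    warning(sum(is.infinite(t)),
            " gene(s) with zero variance but unequal means; ",
            "they take the extreme rank in the direction of the difference")
  }
  stats::setNames(t, rownames(expr))
}

# Vectorized two-sample t over rows; the permutation loop calls this with
# fresh index sets, so it avoids any per-gene apply.
.t_stat_rows <- function(expr, idx1, idx0, var_equal = TRUE) {
  n1 <- length(idx1); n0 <- length(idx0)
  x1 <- expr[, idx1, drop = FALSE]
  x0 <- expr[, idx0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss1 <- rowSums(x1 * x1) - n1 * m1 * m1
  ss0 <- rowSums(x0 * x0) - n0 * m0 * m0
  # guard tiny negative sums of squares from floating-point cancellation
  ss1[ss1 < 0] <- 0; ss0[ss0 < 0] <- 0
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- (ss1 + ss0) / (n1 + n0 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  } else {
    se <- sqrt(ss1 / (n1 * (n1 - 1L)) + ss0 / (n0 * (n0 - 1L)))
  }
  t <- diff / se
  t[se == 0 & diff == 0] <- 0
  t[se == 0 & diff > 0] <- Inf
  t[se == 0 & diff < 0] <- -Inf
  t
}

#' Rank-transform gene scores
#'
#' Ascending average-tie ranks of the t-statistics: the most
#' tumor-downregulated gene gets rank 1 and the most upregulated gets
#' rank G. Infinite scores (zero-variance genes with unequal means) sort
#' beyond every finite score in their direction, which is the extreme-rank
#' placement documented in [gene_t_statistics()]. Ranks always sum to
#' G(G+1)/2.
#'
#' @param t Numeric vector of gene scores (may contain `+/-Inf`).
#' @return Numeric rank vector with the same names.
#' @export
rank_scores <- function(t) {
  rank(t, ties.method = "average")
}
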