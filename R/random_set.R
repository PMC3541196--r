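#' Exact null moments of a mean of scores drawn without replacement
#'
#' The Random-Set null asks: if n genes were picked at random from the G
#' genes on the array, what would the mean of their gene-level scores
#' look like? Simple-random-sampling theory gives the answer in closed
#' form. With population mean \eqn{\mu} and population variance
#' \eqn{\sigma^2 = \frac{1}{G}\sum_g (x_g - \mu)^2} of the G scores,
#' the mean of n scores drawn without replacement has
#' \deqn{\mu_0 = \mu, \qquad
#'       \sigma_0^2 = \frac{\sigma^2}{n}\cdot\frac{G-n}{G-1},}
#' the finite-population-corrected variance of a sample mean. The moments
#' are computed from the realized score vector, so average-tie ranks are
#' handled exactly; for untied ranks 1..G this reduces to
#' \eqn{\mu_0 = (G+1)/2} and \eqn{\sigma_0^2 = (G+1)(G-n)/(12n)}.
#'
#' @param scores Numeric vector of the G gene-level scores (typically
#'   ranks from [rank_scores()]).
#' @param n Set size, with 1 <= n < G; n = G makes the null degenerate
#'   (zero variance) and is an error.
#' @return List with elements `mu0` and `sigma0`.
#' @export
rs_null_moments <- function(scores, n) {
  G <- length(scores)
  if (n < 1L) stop("set size n must be at least 1")
  if (n >= G) stop("degenerate null: zero variance (n must be < G)")
  mu0 <- mean(scores)
  pop_var <- mean((scores - mu0)^2)
  sigma0 <- sqrt(pop_var * (G - n) / ((G - 1) * n))
  list(mu0 = mu0, sigma0 = sigma0)
}

#' Random-Set enrichment score for one gene set
#'
#' Standardizes the mean gene-level score of the set's members against
#' the exact moments from [rs_null_moments()]:
#' \deqn{z = \frac{\bar{x} - \mu_0}{\sigma_0}.}
#' With ranks of tumor-vs-normal t-statistics as scores, positive z means
#' the set's genes sit high in the ranking (tumor upregulation of the
#' pathway) and negative z means downregulation.
#'
#' @param scores Named numeric vector of gene-level scores for the whole
#'   array (names are gene identifiers).
#' @param members Character vector of the set's member identifiers; only
#'   members present among the score names count (effective size).
#' @param name Optional set name carried into the result.
#' @return List with `name`, `n` (effective size), `xbar`, `mu0`,
#'   `sigma0`, `z`, or NULL (with a warning) when no member is on the
#'   array.
#' @export
rs_score <- function(scores, members, name = NA_character_) {
  hit <- unique(members)
  hit <- hit[hit %in% names(scores)]
  if (length(hit) == 0L) {
    warning("gene set ", name, " has no members on the array; skipped")
    return(NULL)
  }
  mom <- rs_null_moments(scores, length(hit))
  xbar <- mean(scores[hit])
  list(name = name, n = length(hit), xbar = xbar,
       mu0 = mom$mu0, sigma0 = mom$sigma0,
       z = (xbar - mom$mu0) / mom$sigma0)
}

#' Gaussian tail p-value for a Random-Set z-score
#'
#' The standardized mean of a moderately large random set is
#' approximately Gaussian, so a one-sided standard-normal tail p-value
#' (upper tail for z > 0, lower tail for z < 0) is a cheap analytic
#' diagnostic. The headline nominal p-values of the pipeline come from
#' phenotype-label permutation ([rs_enrichment()]); this analytic p is
#' reported alongside them.
#'
#' @param z Numeric vector of z-scores.
#' @return One-sided tail probabilities; z = 0 gives 0.5.
#' @export
rs_gaussian_pvalue <- function(z) {
  stats::pnorm(-abs(z))
}

# Sparse genes-x-sets membership indicator used by the permutation loop:
# column j marks the effective members of set j among `genes`.
.membership_matrix <- function(sets, genes) {
  idx <- lapply(sets, function(s) which(genes %in% s))
  j <- rep.int(seq_along(idx), lengths(idx))
  Matrix::sparseMatrix(i = unlist(idx), j = j,
                       dims = c(length(genes), length(sets)),
                       dimnames = list(NULL, names(sets)))
}

# z-scores for every set given one score vector; M is the membership
# matrix and n the per-set effective sizes. Vectorizes rs_score.
.rs_z_all <- function(scores, M, n) {
  G <- length(scores)
  mu0 <- mean(scores)
  pop_var <- mean((scores - mu0)^2)
  xbar <- as.numeric(Matrix::crossprod(M, scores)) / n
  sigma0 <- sqrt(pop_var * (G - n) / ((G - 1) * n))
  (xbar - mu0) / sigma0
}
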