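# Run fn() with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package functions never disturb the session stream.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Random-Set enrichment with phenotype-permutation p-values
#'
#' The full per-contrast pipeline: per-gene two-sample t-statistics,
#' their average-tie ranks, a Random-Set z per gene set, and a nominal
#' p-value for each z from B permutations of the phenotype labels. Each
#' permutation shuffles the 0/1 labels (class sizes fixed by
#' construction), recomputes every t-statistic, re-ranks, and rescores
#' every set, so the permutation distribution reflects the whole
#' pipeline and preserves inter-gene correlation. One label permutation
#' scores all sets, which makes results seed-stable and independent of
#' set order.
#'
#' The p-value is one-sided in the direction of the observed z: for
#' z_obs > 0 it is the permutation tail count `#{z_b >= z_obs}` divided
#' by the number of same-signed permutations `#{z_b >= 0}`, and mirrored
#' for z_obs < 0 — the standard estimator for signed enrichment
#' statistics (GSEA normalizes its nominal p the same way). Dividing by
#' the same-sign count rather than by B keeps the null distribution of
#' the reported p uniform on (0, 1), so the fraction of null sets with
#' p < alpha is alpha rather than 2 alpha, while the up and down calls
#' stay disjoint. The plug-in estimator (default) can be exactly 0 when
#' no permuted score reaches the observed one; the smoothed estimator
#' (b+1)/(B_same+1) never is, and is preferable when p-values feed
#' further inference. A set is called `up` when z_obs > 0 and p < alpha,
#' `down` when z_obs < 0 and p < alpha, otherwise `none`.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels 0/1 phenotype vector (0 = normal, 1 = tumor).
#' @param sets Named list of gene sets (character vectors of gene ids).
#' @param B Number of label permutations (default 1000).
#' @param alpha Significance cutoff on the nominal p-value (default 0.05).
#' @param seed Integer seed making the permutation stream reproducible.
#' @param estimator `"plugin"` for b/B_same or `"smoothed"` for
#'   (b+1)/(B_same+1), B_same being the same-signed permutation count.
#' @param two_sided Report two-sided p-values, the fraction of
#'   permutations with |z_b| >= |z_obs| (denominator B), instead of the
#'   one-sided ones. Default FALSE: the up and down calls are disjoint
#'   one-sided tests each gated at alpha.
#' @param var_equal Pooled (TRUE) or Welch (FALSE) t-statistics.
#' @param min_size,max_size Effective-size filter applied after
#'   intersecting each set with the array. Defaults keep every set with
#'   at least one member, mirroring printed pathway tables that include
#'   sets as small as n = 8.
#' @return Data frame with one row per retained set: `pathway`, `n`,
#'   `xbar`, `z`, `p_analytic` (Gaussian diagnostic), `p` (permutation),
#'   `p_bh` (Benjamini-Hochberg adjusted, informational only — calls are
#'   gated on the nominal p), `direction`.
#' @export
rs_enrichment <- function(expr, labels, sets, B = 1000L, alpha = 0.05,
                          seed = NULL, estimator = c("plugin", "smoothed"),
                          two_sided = FALSE, var_equal = TRUE,
                          min_size = 1L, max_size = Inf) {
  estimator <- match.arg(estimator)
  validate_labels(labels, expr)
  if (B < 1L) stop("B must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (B < 100L) {
    warning("B = ", B, " permutations cannot resolve p-values below 1/",
            B, "; alpha-level calls will be coarse")
  }

  genes <- rownames(expr)
  n_eff <- effective_sizes(sets, expr)
  empty <- n_eff == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) with no members on the array skipped: ",
            paste(names(sets)[empty], collapse = ", "))
  }
  keep <- !empty & n_eff >= min_size & n_eff <= max_size
  sets <- sets[keep]
  n_eff <- n_eff[keep]
  if (length(sets) == 0L) stop("no gene sets left after filtering")

  M <- .membership_matrix(sets, genes)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  score_once <- function(i1, i0) {
    t <- .t_stat_rows(expr, i1, i0, var_equal = var_equal)
    .rs_z_all(rank_scores(t), M, n_eff)
  }
  r_obs <- rank_scores(.t_stat_rows(expr, idx1, idx0, var_equal = var_equal))
  xbar_obs <- as.numeric(Matrix::crossprod(M, r_obs)) / n_eff
  z_obs <- .rs_z_all(r_obs, M, n_eff)

  n1 <- length(idx1)
  S <- ncol(expr)
  counts <- .with_seed(seed, function() {
    k <- length(sets)
    ge <- integer(k)      # permuted z >= observed
    le <- integer(k)      # permuted z <= observed
    pos <- integer(k)     # permuted z >= 0
    neg <- integer(k)     # permuted z <= 0
    abs_ge <- integer(k)  # |permuted z| >= |observed|
    for (b in seq_len(B)) {
      i1 <- sample.int(S, n1)
      z_b <- score_once(i1, setdiff(seq_len(S), i1))
      ge <- ge + (z_b >= z_obs)
      le <- le + (z_b <= z_obs)
      pos <- pos + (z_b >= 0)
      neg <- neg + (z_b <= 0)
      abs_ge <- abs_ge + (abs(z_b) >= abs(z_obs))
    }
    list(ge = ge, le = le, pos = pos, neg = neg, abs_ge = abs_ge)
  })

  p <- .perm_p(counts, z_obs, B, estimator, two_sided)

  direction <- enrichment_call(z_obs, p, alpha)
  data.frame(
    pathway = names(sets),
    n = as.integer(n_eff),
    xbar = xbar_obs,
    z = z_obs,
    p_analytic = rs_gaussian_pvalue(z_obs),
    p = p,
    p_bh = stats::p.adjust(p, method = "BH"),
    direction = direction,
    row.names = NULL
  )
}

# Nominal p from permutation tail counts: one-sided in the observed
# direction with a same-sign denominator (keeps the null p uniform), or
# two-sided on |z| with denominator B.
.perm_p <- function(counts, z_obs, B, estimator, two_sided) {
  est <- function(b, denom) {
    if (estimator == "plugin") b / pmax(denom, 1L) else (b + 1) / (denom + 1)
  }
  if (two_sided) return(pmin(1, est(counts$abs_ge, B)))
  p_up <- est(counts$ge, counts$pos)
  p_lo <- est(counts$le, counts$neg)
  pmin(1, ifelse(z_obs >= 0, p_up, p_lo))
}

#' Direction call from a z-score and its p-value
#'
#' `up` for significantly positive scores, `down` for significantly
#' negative ones, `none` otherwise.
#'
#' @param z Numeric vector of enrichment scores (sign carries direction).
#' @param p Nominal p-values in the same order.
#' @param alpha Significance cutoff (default 0.05).
#' @return Character vector in `c("up", "down", "none")`.
#' @export
enrichment_call <- function(z, p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < alpha, ifelse(z > 0, "up", ifelse(z < 0, "down", "none")),
         "none")
}
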