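#' Weighted Kolmogorov-Smirnov (GSEA) enrichment score
#'
#' The classic running-sum enrichment score over a gene list ranked by a
#' gene-level metric (largest first). Walking down the list, the sum
#' rises by \eqn{|m_g|^q / N_R} at each set member (hit), where
#' \eqn{N_R = \sum_{hits} |m_g|^q}, and falls by \eqn{1/(G-n)} at each
#' non-member (miss). The enrichment score is the running sum's maximum
#' deviation from zero, signed. With q = 0 (and untied metrics) this is
#' exactly the two-sample Kolmogorov-Smirnov statistic between hit and
#' miss positions.
#'
#' @param metric Named numeric gene-level metric (e.g. signal-to-noise or
#'   t); names are gene identifiers. Internally sorted decreasing.
#' @param members Character vector of set members; only those present in
#'   `metric` count.
#' @param q Weight exponent >= 0; 1 (default) is the standard weighted
#'   statistic, 0 the unweighted KS form.
#' @return List with `es` (the signed score, in \[-1, 1\]) and `n` (the
#'   effective number of hits), or NULL if the set misses the list
#'   entirely.
#' @export
gsea_enrichment_score <- function(metric, members, q = 1) {
  stopifnot(q >= 0)
  ord <- order(metric, decreasing = TRUE)
  m_sorted <- metric[ord]
  hit <- names(m_sorted) %in% unique(members)
  n <- sum(hit)
  G <- length(metric)
  if (n == 0L) return(NULL)
  if (n == G) stop("set covers the whole list; miss decrement undefined")
  w <- abs(m_sorted)^q
  nr <- sum(w[hit])
  if (nr == 0) {
    # all-zero hit weights: fall back to equal hit increments
    inc <- ifelse(hit, 1 / n, -1 / (G - n))
  } else {
    inc <- ifelse(hit, w / nr, -1 / (G - n))
  }
  walk <- cumsum(inc)
  es <- walk[[which.max(abs(walk))]]
  list(es = es, n = n)
}

#' GSEA-style enrichment with phenotype-permutation p-values
#'
#' The validation arm of the pipeline: an independent enrichment method
#' sharing only the permutation design with the Random-Set arm. Genes
#' are scored by a two-class metric (signal-to-noise by default, the
#' common GSEA choice; pooled t for symmetry with the RS arm), the
#' weighted KS score of each set is computed, and nominal one-sided
#' p-values come from B label permutations, with direction called as in
#' [enrichment_call()].
#'
#' @inheritParams rs_enrichment
#' @param q Weight exponent passed to [gsea_enrichment_score()].
#' @param metric `"s2n"` (signal-to-noise) or `"t"` (pooled t).
#' @return Data frame: `pathway`, `n`, `es`, `p`, `direction`.
#' @export
gsea_enrichment <- function(expr, labels, sets, B = 1000L, alpha = 0.05,
                            seed = NULL, q = 1, metric = c("s2n", "t"),
                            estimator = c("plugin", "smoothed")) {
  metric <- match.arg(metric)
  estimator <- match.arg(estimator)
  validate_labels(labels, expr)
  genes <- rownames(expr)
  n_eff <- effective_sizes(sets, expr)
  empty <- n_eff == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) with no members on the array skipped")
    sets <- sets[!empty]
    n_eff <- n_eff[!empty]
  }
  hits <- lapply(sets, function(s) genes %in% s)

  metric_fun <- function(i1, i0) {
    if (metric == "t") {
      .t_stat_rows(expr, i1, i0, var_equal = TRUE)
    } else {
      .s2n_rows(expr, i1, i0)
    }
  }
  es_all <- function(i1, i0) {
    m <- stats::setNames(metric_fun(i1, i0), genes)
    ord <- order(m, decreasing = TRUE)
    w_sorted <- abs(m[ord])^q
    vapply(hits, function(h) .es_from_walk(h[ord], w_sorted), numeric(1))
  }

  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  es_obs <- es_all(idx1, idx0)

  S <- ncol(expr); n1 <- length(idx1)
  counts <- .with_seed(seed, function() {
    k <- length(sets)
    ge <- integer(k); le <- integer(k); pos <- integer(k); neg <- integer(k)
    abs_ge <- integer(k)
    for (b in seq_len(B)) {
      i1 <- sample.int(S, n1)
      es_b <- es_all(i1, setdiff(seq_len(S), i1))
      ge <- ge + (es_b >= es_obs)
      le <- le + (es_b <= es_obs)
      pos <- pos + (es_b >= 0)
      neg <- neg + (es_b <= 0)
      abs_ge <- abs_ge + (abs(es_b) >= abs(es_obs))
    }
    list(ge = ge, le = le, pos = pos, neg = neg, abs_ge = abs_ge)
  })
  p <- .perm_p(counts, es_obs, B, estimator, two_sided = FALSE)
  data.frame(pathway = names(sets), n = as.integer(n_eff), es = es_obs,
             p = p, direction = enrichment_call(es_obs, p, alpha),
             row.names = NULL)
}

# Signed-max running sum given a hit indicator and |metric|^q, both in
# list order (largest metric first).
.es_from_walk <- function(hit, w) {
  n <- sum(hit); G <- length(hit)
  if (n == 0L || n == G) return(NA_real_)
  nr <- sum(w[hit])
  inc <- if (nr == 0) ifelse(hit, 1 / n, -1 / (G - n)) else
    ifelse(hit, w / nr, -1 / (G - n))
  walk <- cumsum(inc)
  walk[[which.max(abs(walk))]]
}

# Signal-to-noise metric: (m1 - m0) / (s1 + s0), with each sd floored at
# max(0.2 * |class mean|, 0.2) as in the common GSEA implementation, so
# low-variance genes do not dominate.
.s2n_rows <- function(expr, idx1, idx0) {
  x1 <- expr[, idx1, drop = FALSE]; x0 <- expr[, idx0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s1 <- apply(x1, 1L, stats::sd); s0 <- apply(x0, 1L, stats::sd)
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s0 <- pmax(s0, 0.2 * abs(m0), 0.2)
  (m1 - m0) / (s1 + s0)
}

#' Overlap of two enriched-pathway lists with a Fisher exact p-value
#'
#' Builds the 2x2 in-A by in-B table over a universe of pathways and
#' reports the overlap count, the overlap fraction relative to list A,
#' and the one-sided (upper-tail) hypergeometric p-value for seeing at
#' least that much overlap by chance — Fisher's exact test with the
#' greater alternative.
#'
#' @param list_a,list_b Character vectors of pathway names.
#' @param universe_size Number of pathways tested in both analyses (the
#'   2x2 table's total); must be at least the size of the union.
#' @return List: `universe`, `n_a`, `n_b`, `overlap`, `fraction`
#'   (overlap / n_a), `p`.
#' @export
overlap_fisher <- function(list_a, list_b, universe_size) {
  a <- unique(list_a); b <- unique(list_b)
  k <- length(intersect(a, b))
  if (universe_size < length(union(a, b))) {
    stop("universe smaller than the union of the two lists")
  }
  p <- stats::phyper(k - 1, length(a), universe_size - length(a),
                     length(b), lower.tail = FALSE)
  list(universe = universe_size, n_a = length(a), n_b = length(b),
       overlap = k, fraction = k / length(a), p = p)
}

#' Compare the sizes of up- and down-regulated gene sets
#'
#' Tests whether sets called down-regulated in tumors are larger (in
#' member count) than those called up-regulated, with a one-tailed
#' pooled-variance two-sample t-test (alternative: mean size of the
#' down list exceeds that of the up list).
#'
#' @param sizes_up,sizes_down Integer vectors of effective set sizes.
#' @return List: `mean_up`, `mean_down`, `p` (one-tailed).
#' @export
setsize_comparison <- function(sizes_up, sizes_down) {
  stopifnot(length(sizes_up) > 0L, length(sizes_down) > 0L)
  ht <- stats::t.test(sizes_down, sizes_up, alternative = "greater",
                      var.equal = TRUE)
  list(mean_up = mean(sizes_up), mean_down = mean(sizes_down),
       p = ht$p.value)
}
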