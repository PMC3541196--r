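test_that("running-sum score matches the hand walk and its bounds", {
  metric <- stats::setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  es <- gsea_enrichment_score(metric, c("g1", "g2"), q = 0)
  expect_equal(es$es, 1.0)  # walk 0.5, 1.0, 0.5, 0
  expect_identical(es$n, 2L)

  expect_error(gsea_enrichment_score(metric, paste0("g", 1:4)),
               "whole list")
  expect_null(gsea_enrichment_score(metric, c("gX")))

  # uniformly interleaved set with equal weights stays within the
  # single-step bound 1/n + 1/(G-n)
  interleaved <- stats::setNames(20:1, paste0("g", 1:20))
  hits <- paste0("g", seq(1, 20, by = 2))
  es_i <- gsea_enrichment_score(interleaved, hits, q = 0)
  expect_lte(abs(es_i$es), 1 / 10 + 1 / 10 + 1e-12)
})

test_that("vectorized score equals the brute-force walk on random cases", {
  set.seed(31)
  for (i in 1:25) {
    G <- sample(10:60, 1)
    metric <- stats::setNames(rnorm(G), sprintf("g%03d", 1:G))
    n <- sample(2:(G - 2), 1)
    members <- sample(names(metric), n)
    hit <- names(metric) %in% members
    for (q in c(0, 1, 2)) {
      es <- gsea_enrichment_score(metric, members, q = q)
      expect_equal(es$es, walk_es(metric, hit, q), tolerance = 1e-12)
    }
  }
})

test_that("q = 0 reduces to the two-sample KS statistic of hit positions", {
  set.seed(32)
  for (i in 1:20) {
    G <- sample(10:50, 1)
    metric <- stats::setNames(rnorm(G), sprintf("g%03d", 1:G))
    n <- sample(2:(G - 2), 1)
    members <- sample(names(metric), n)
    es <- gsea_enrichment_score(metric, members, q = 0)
    pos <- which(names(sort(metric, decreasing = TRUE)) %in% members)
    D <- suppressWarnings(
      ks.test(pos, setdiff(seq_len(G), pos))$statistic
    )
    expect_equal(abs(es$es), unname(D), tolerance = 1e-10)
  }
})

test_that("weighted score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  for (i in 1:10) {
    G <- 100
    metric <- sort(stats::setNames(rnorm(G), sprintf("g%03d", 1:G)),
                   decreasing = TRUE)
    members <- sample(names(metric), 15)
    es <- gsea_enrichment_score(metric, members, q = 1)
    ref <- fgsea::calcGseaStat(unname(metric),
                               which(names(metric) %in% members),
                               gseaParam = 1)
    expect_equal(es$es, ref, tolerance = 1e-10)
  }
})

test_that("GSEA permutation arm recovers planted sets deterministically", {
  sim <- planted_sim(seed = 34, delta = 2, f = 1, n_set = 20,
                     G = 500, n_per_class = 15, n_sets = 8)
  g1 <- gsea_enrichment(sim$expr, sim$labels, sim$sets, B = 200, seed = 5)
  g2 <- gsea_enrichment(sim$expr, sim$labels, sim$sets, B = 200, seed = 5)
  expect_identical(g1, g2)
  expect_identical(g1$direction[g1$pathway == "set001"], "up")
  expect_identical(g1$direction[g1$pathway == "set002"], "down")
  expect_gt(g1$es[g1$pathway == "set001"], 0)
  expect_lt(g1$es[g1$pathway == "set002"], 0)
})

test_that("RS and GSEA agree in direction on fully planted sets", {
  agree <- 0L
  for (rep in 1:30) {
    sim <- planted_sim(seed = 400 + rep, delta = 2, f = 1, n_set = 20,
                       G = 500, n_per_class = 15, n_sets = 5)
    t <- gene_t_statistics(sim$expr, sim$labels)
    z_up <- rs_score(rank_scores(t), sim$sets$set001)$z
    z_dn <- rs_score(rank_scores(t), sim$sets$set002)$z
    es_up <- gsea_enrichment_score(t, sim$sets$set001)$es
    es_dn <- gsea_enrichment_score(t, sim$sets$set002)$es
    agree <- agree + (sign(z_up) == sign(es_up) &&
                        sign(z_dn) == sign(es_dn))
  }
  expect_gte(agree / 30, 0.95)
})

test_that("Fisher overlap handles the extremes and checks its universe", {
  same <- overlap_fisher(paste0("p", 1:10), paste0("p", 1:10), 100)
  expect_identical(same$overlap, 10L)
  expect_identical(same$fraction, 1)
  expect_equal(same$p, 1 / choose(100, 10), tolerance = 1e-9)

  disj <- overlap_fisher(paste0("a", 1:3), paste0("b", 1:3), 1000)
  expect_identical(disj$overlap, 0L)
  expect_equal(disj$p, 1)

  expect_error(overlap_fisher(paste0("a", 1:3), paste0("b", 1:3), 5),
               "universe")
})

test_that("hypergeometric p agrees with a log-factorial oracle", {
  # independent exact-summation oracle built from lgamma
  log_hyper_tail <- function(k, A, B, N) {
    lchoose2 <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
    terms <- vapply(k:min(A, B), function(x) {
      lchoose2(A, x) + lchoose2(N - A, B - x) - lchoose2(N, B)
    }, numeric(1))
    m <- max(terms)
    exp(m) * sum(exp(terms - m))
  }
  # published-margin case: 33 and 107 enriched lists over 880 pathways,
  # 24 shared
  A <- paste0("p", 1:33)
  B <- c(paste0("p", 1:24), paste0("q", 1:83))
  ov <- overlap_fisher(A, B, 880)
  expect_identical(ov$overlap, 24L)
  expect_equal(ov$fraction, 24 / 33, tolerance = 1e-12)
  oracle <- log_hyper_tail(24, 33, 107, 880)
  expect_equal(ov$p, oracle, tolerance = 1e-10)
  # and a third route: fisher.test one-sided
  tab <- matrix(c(24, 33 - 24, 107 - 24, 880 - 33 - 107 + 24), 2, 2)
  expect_equal(ov$p, fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("set-size comparison reports means and a one-tailed pooled t", {
  up <- c(10, 12, 14); down <- c(30, 31, 35)
  cmp <- setsize_comparison(up, down)
  expect_equal(cmp$mean_up, 12)
  expect_equal(cmp$mean_down, 32)
  # hand-computed pooled t for these vectors
  sp2 <- (var(up) * 2 + var(down) * 2) / 4
  t_hand <- (32 - 12) / sqrt(sp2 * (2 / 3))
  expect_equal(cmp$p, pt(t_hand, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical vectors: one-tailed p = 0.5
  expect_equal(setsize_comparison(c(5, 7, 9), c(5, 7, 9))$p, 0.5)
})
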