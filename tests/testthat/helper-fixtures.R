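# Small in-code fixtures shared across test files.

# 3-gene x 4-sample expression matrix with easy hand-checkable values
toy_expression <- function() {
  m <- matrix(c(1.5, 2.5, 3.5, 4.5,
                2.0, 2.0, 2.0, 2.0,
                8.25, 7.75, 6.5, 5.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  m
}

write_toy_gct <- function(path = tempfile(fileext = ".gct")) {
  write_expression(toy_expression(), path, format = "gct")
  path
}

write_lines_tmp <- function(lines, fileext = ".txt") {
  path <- tempfile(fileext = fileext)
  writeLines(lines, path)
  path
}

# Brute-force oracle: exact moments of the mean of n scores over all
# C(G, n) subsets, by enumeration. Independent of rs_null_moments.
enumerate_subset_moments <- function(scores, n) {
  means <- combn(scores, n, mean)
  list(mu = mean(means), var = mean((means - mean(means))^2))
}

# Brute-force oracle for the GSEA running sum: walk the full list.
walk_es <- function(metric, hit, q) {
  stopifnot(length(metric) == length(hit))
  ord <- order(metric, decreasing = TRUE)
  hit <- hit[ord]
  w <- abs(metric[ord])^q
  n <- sum(hit); G <- length(hit)
  nr <- sum(w[hit])
  inc <- ifelse(hit, if (nr == 0) 1 / n else NA, -1 / (G - n))
  if (nr > 0) inc[hit] <- w[hit] / nr
  walk <- cumsum(inc)
  walk[[which.max(abs(walk))]]
}

# A fixed two-class dataset with one clearly up-shifted set, used where
# tests need planted signal without rebuilding configs each time.
planted_sim <- function(seed = 42, delta = 2, f = 1, n_set = 20,
                        G = 1000, n_per_class = 30, n_sets = 10) {
  cfg <- sim_config(G = G, n_normal = n_per_class, n_tumor = n_per_class,
                    n_sets = n_sets, set_size_range = c(n_set, n_set),
                    planted = list(
                      list(set = 1, direction = "up", delta = delta, f = f),
                      list(set = 2, direction = "down", delta = delta, f = f)
                    ),
                    seed = seed)
  simulate_dataset(cfg)
}
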