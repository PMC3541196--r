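# Builds a three-stage design: shared normals plus SPL/LPL/CRC tumor
# groups, with set001 planted up only in CRC samples and set002 planted
# down at every stage.
three_stage_sim <- function(seed = 51, G = 500, n_per_group = 10,
                            n_set = 20, delta = 2) {
  base <- simulate_dataset(sim_config(
    G = G, n_normal = n_per_group, n_tumor = 3 * n_per_group,
    n_sets = 6, set_size_range = c(n_set, n_set), seed = seed))
  expr <- base$expr
  stage <- c(rep("N", n_per_group),
             rep(c("SPL", "LPL", "CRC"), each = n_per_group))
  colnames(expr) <- sprintf("%s_%02d", stage, seq_along(stage))
  up_members <- base$sets$set001
  dn_members <- base$sets$set002
  expr[up_members, stage == "CRC"] <- expr[up_members, stage == "CRC"] + delta
  expr[dn_members, stage != "N"] <- expr[dn_members, stage != "N"] - delta
  list(expr = expr, stage = stage, sets = base$sets)
}

test_that("stage contrasts recover planted stage-specific trajectories", {
  d <- three_stage_sim()
  out <- run_stage_analysis(d$expr, d$stage, d$sets, B = 200, seed = 6)
  traj <- out$trajectory

  row_up <- traj[traj$pathway == "set001", ]
  expect_identical(unlist(row_up[, c("dir_SPL", "dir_LPL", "dir_CRC")],
                          use.names = FALSE),
                   c("none", "none", "up"))
  expect_identical(row_up$venn_up, "CRC")
  expect_true(is.na(row_up$venn_down))
  # a reported p implies a non-none direction
  expect_true(is.na(row_up$p_SPL) && is.na(row_up$p_LPL))
  expect_lt(row_up$p_CRC, 0.05)

  row_dn <- traj[traj$pathway == "set002", ]
  expect_identical(unlist(row_dn[, c("dir_SPL", "dir_LPL", "dir_CRC")],
                          use.names = FALSE),
                   c("down", "down", "down"))
  expect_identical(row_dn$venn_down, "SPL+LPL+CRC")

  # per-stage attribute and contract: stage result is an rs_enrichment table
  expect_identical(attr(out$per_stage$LPL, "stage"), "LPL")
  expect_identical(out$per_stage$CRC$direction[
    out$per_stage$CRC$pathway == "set001"], "up")
})

test_that("null pathways stay unflagged in most replicates", {
  # three independent contrasts at alpha = 0.05: a null set survives all
  # of them with probability (1 - alpha)^3 ~ 0.857
  calls <- 0L; total <- 0L
  for (rep in 1:10) {
    d <- three_stage_sim(seed = 600 + rep, G = 300, n_per_group = 8,
                         delta = 0)
    out <- run_stage_analysis(d$expr, d$stage, d$sets, B = 100,
                              seed = rep)
    none_rows <- out$trajectory
    flagged <- !is.na(none_rows$venn_up) | !is.na(none_rows$venn_down)
    calls <- calls + sum(!flagged)
    total <- total + nrow(none_rows)
  }
  expect_gte(calls / total, 0.7)  # 3 SEs below the expected 0.857 at n=60
})

test_that("Venn counts conserve per-stage marginals", {
  d <- three_stage_sim(seed = 52)
  out <- run_stage_analysis(d$expr, d$stage, d$sets, B = 150, seed = 3)
  counts <- venn_counts(out$trajectory)
  marg <- venn_marginals(counts)
  for (st in c("SPL", "LPL", "CRC")) {
    res <- out$per_stage[[st]]
    expect_identical(unname(marg["up", st]),
                     sum(res$direction == "up"))
    expect_identical(unname(marg["down", st]),
                     sum(res$direction == "down"))
  }
})

test_that("degenerate Venn inputs behave", {
  empty <- data.frame(venn_up = character(0), venn_down = character(0))
  expect_true(all(venn_counts(empty) == 0L))
  one <- data.frame(venn_up = "SPL+LPL+CRC", venn_down = NA_character_)
  counts <- venn_counts(one)
  expect_identical(unname(counts["up", "SPL+LPL+CRC"]), 1L)
  expect_identical(sum(counts), 1L)
  expect_true(all(venn_marginals(counts)["up", ] == 1L))
})

test_that("published stage tables reproduce the printed stage counts", {
  tabs <- crc_stage_tables()
  traj <- trajectory_from_tables(tabs$up, tabs$down)
  marg <- venn_marginals(venn_counts(traj))
  expect_identical(unname(marg["up", ]), c(23L, 21L, 33L))
  expect_identical(unname(marg["down", ]), c(41L, 29L, 25L))
  expect_identical(nrow(traj), 112L)
})

test_that("two-cluster diagnostic separates well-separated groups", {
  set.seed(53)
  X <- cbind(matrix(rnorm(20 * 8, 0), 20, 8),
             matrix(rnorm(20 * 8, 5), 20, 8))
  dimnames(X) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:16))
  labels <- rep(c(0L, 1L), each = 8)
  diag <- cluster_diagnostic(X, labels)
  expect_identical(diag$misclassified, 0L)
  expect_identical(unname(diag$assignment), labels)
  # deterministic
  expect_identical(cluster_diagnostic(X, labels)$misclassified, 0L)
  expect_lte(diag$misclassified, floor(16 / 2))

  expect_error(cluster_diagnostic(X[1, , drop = FALSE], labels), "2 genes")
  expect_error(cluster_diagnostic(X[, 1:2], labels[1:2]), "3 samples")
})

test_that("cluster misclassification under no structure is substantial", {
  set.seed(54)
  mis <- replicate(20, {
    X <- matrix(rnorm(15 * 20), 15, 20,
                dimnames = list(sprintf("g%02d", 1:15),
                                sprintf("s%02d", 1:20)))
    cluster_diagnostic(X, rep(c(0L, 1L), each = 10))$misclassified
  })
  expect_gt(mean(mis) / 20, 0.15)   # far from perfect separation
  expect_true(all(mis <= 10))       # never beyond floor(S/2)
})

test_that("PCA projection centers genes and orders variance", {
  # rank-1 matrix: one component explains everything
  u <- rnorm(6); v <- rnorm(10)
  X <- outer(u, v)
  dimnames(X) <- list(paste0("g", 1:6), paste0("s", 1:10))
  p <- pca_projection(X)
  expect_equal(p$explained[[1]], 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_identical(dim(p$coords), c(10L, 2L))

  # invariant to per-gene mean shifts
  p2 <- pca_projection(X + rnorm(6))
  expect_equal(abs(p$coords), abs(p2$coords), tolerance = 1e-8)

  # two isotropic genes split the variance evenly (within MC tolerance)
  set.seed(55)
  Y <- matrix(rnorm(2 * 4000), 2, 4000,
              dimnames = list(c("g1", "g2"), sprintf("s%04d", 1:4000)))
  py <- pca_projection(Y)
  expect_lt(abs(py$explained[[1]] - 0.5), 0.05)

  Z <- matrix(1, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  expect_error(pca_projection(Z), "constant")
})
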