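#' Run one stage contrast (normal vs one tumor stage)
#'
#' Thin wrapper over [rs_enrichment()] that subsets the expression
#' matrix to the normal samples plus the samples of one tumor stage and
#' tags the result with the stage, so that three calls (SPL, LPL, CRC
#' against the shared normals) assemble into a trajectory table.
#'
#' @param expr Expression matrix over all samples.
#' @param sample_stage Character vector per column of `expr`, each one
#'   of `"N"`, `"SPL"`, `"LPL"`, `"CRC"`.
#' @param stage The tumor stage to contrast against the normals.
#' @param sets Named list of gene sets.
#' @param ... Passed to [rs_enrichment()] (B, alpha, seed, ...).
#' @return The [rs_enrichment()] data frame with a `stage` attribute.
#' @export
run_stage_contrast <- function(expr, sample_stage, stage = c("SPL", "LPL", "CRC"),
                               sets, ...) {
  stage <- match.arg(stage)
  stopifnot(length(sample_stage) == ncol(expr))
  keep <- sample_stage %in% c("N", stage)
  sub <- expr[, keep, drop = FALSE]
  labels <- phenotype_labels(as.integer(sample_stage[keep] == stage),
                             sample_ids = colnames(sub), stage = stage)
  res <- rs_enrichment(sub, labels, sets, ...)
  attr(res, "stage") <- stage
  res
}

#' Run all three stage contrasts and assemble the trajectory table
#'
#' Each tumor stage is contrasted independently against the shared
#' normal samples, exactly as in a progressive tumorigenesis design.
#' The per-stage results are merged into one row per pathway with
#' per-stage p-values (NA where not significant, matching printed
#' tables) and direction calls, plus the Venn-partition cell for each
#' direction.
#'
#' @inheritParams run_stage_contrast
#' @param stages Stages to run (default all three).
#' @return List with `per_stage` (named list of [rs_enrichment()]
#'   results) and `trajectory` (see [trajectory_table()]).
#' @export
run_stage_analysis <- function(expr, sample_stage, sets,
                               stages = c("SPL", "LPL", "CRC"), ...) {
  per_stage <- lapply(stages, function(st) {
    run_stage_contrast(expr, sample_stage, st, sets, ...)
  })
  names(per_stage) <- stages
  list(per_stage = per_stage, trajectory = trajectory_table(per_stage))
}

#' Build the cross-stage trajectory table
#'
#' Combines per-stage enrichment results into one row per pathway:
#' direction calls and p-values at each stage (p kept only where the
#' call is non-none, so a reported p always implies a direction), and
#' the Venn cell — the combination of stages at which the pathway is
#' significant — separately for the up and down directions.
#'
#' @param per_stage Named list of [rs_enrichment()] results; names are
#'   stages among SPL, LPL, CRC.
#' @return Data frame with columns `pathway`, `n`, then `dir_<stage>`
#'   and `p_<stage>` per stage, and `venn_up`, `venn_down` (e.g.
#'   `"SPL+LPL"`, or NA when never significant in that direction).
#' @export
trajectory_table <- function(per_stage) {
  stages <- names(per_stage)
  stopifnot(length(stages) >= 1L, all(stages %in% c("SPL", "LPL", "CRC")))
  pathways <- unique(unlist(lapply(per_stage, `[[`, "pathway")))
  out <- data.frame(pathway = pathways,
                    n = per_stage[[1L]]$n[match(pathways,
                                                per_stage[[1L]]$pathway)])
  for (st in stages) {
    res <- per_stage[[st]]
    i <- match(pathways, res$pathway)
    dir <- res$direction[i]
    dir[is.na(dir)] <- "none"
    p <- res$p[i]
    p[dir == "none"] <- NA_real_
    out[[paste0("dir_", st)]] <- dir
    out[[paste0("p_", st)]] <- p
  }
  dir_mat <- as.matrix(out[, paste0("dir_", stages), drop = FALSE])
  colnames(dir_mat) <- stages
  out$venn_up <- apply(dir_mat, 1L, .venn_cell, direction = "up")
  out$venn_down <- apply(dir_mat, 1L, .venn_cell, direction = "down")
  out
}

.venn_cell <- function(dirs, direction) {
  st <- names(dirs)[dirs == direction]
  if (length(st) == 0L) NA_character_ else paste(st, collapse = "+")
}

#' Venn-partition counts of stage trajectories
#'
#' Counts, for each direction, how many pathways fall in each of the 7
#' non-empty cells of the three-stage Venn diagram. Marginal per-stage
#' counts (`SPL` cell + every cell containing SPL, etc.) always equal
#' the number of pathways significant at that stage in that direction.
#'
#' @param trajectory Output of [trajectory_table()] (or any data frame
#'   with `venn_up`/`venn_down` columns built over stages SPL, LPL, CRC).
#' @return Integer matrix, rows `up`/`down`, columns the 7 Venn cells
#'   `SPL`, `LPL`, `CRC`, `SPL+LPL`, `SPL+CRC`, `LPL+CRC`,
#'   `SPL+LPL+CRC`.
#' @export
venn_counts <- function(trajectory) {
  cells <- c("SPL", "LPL", "CRC", "SPL+LPL", "SPL+CRC", "LPL+CRC",
             "SPL+LPL+CRC")
  counts <- rbind(
    up = table(factor(trajectory$venn_up, levels = cells)),
    down = table(factor(trajectory$venn_down, levels = cells))
  )
  colnames(counts) <- cells
  counts
}

#' Per-stage significant counts from a Venn count matrix
#'
#' @param counts Matrix from [venn_counts()].
#' @return Integer matrix, rows `up`/`down`, columns `SPL`, `LPL`,
#'   `CRC`: the number of pathways significant at each stage.
#' @export
venn_marginals <- function(counts) {
  stages <- c("SPL", "LPL", "CRC")
  out <- sapply(stages, function(st) {
    has <- vapply(colnames(counts),
                  function(cell) st %in% strsplit(cell, "+", fixed = TRUE)[[1L]],
                  logical(1))
    rowSums(counts[, has, drop = FALSE])
  })
  storage.mode(out) <- "integer"
  out
}

#' Trajectory table from printed-style result tables
#'
#' Converts per-stage p-value tables in the printed layout (one table of
#' upregulated pathways, one of downregulated; NA cells where not
#' significant) into the same trajectory structure produced by
#' [trajectory_table()], so Venn counts and marginals can be computed
#' from published tables and from pipeline output alike.
#'
#' @param up,down Data frames with columns `pathway`, `n`, `p_SPL`,
#'   `p_LPL`, `p_CRC` (e.g. from [crc_stage_tables()]).
#' @return Data frame in [trajectory_table()] layout.
#' @export
trajectory_from_tables <- function(up, down) {
  build <- function(tbl, direction) {
    out <- tbl[, c("pathway", "n")]
    for (st in c("SPL", "LPL", "CRC")) {
      p <- tbl[[paste0("p_", st)]]
      out[[paste0("dir_", st)]] <- ifelse(is.na(p), "none", direction)
      out[[paste0("p_", st)]] <- p
    }
    out
  }
  out <- rbind(build(up, "up"), build(down, "down"))
  dir_mat <- as.matrix(out[, paste0("dir_", c("SPL", "LPL", "CRC"))])
  colnames(dir_mat) <- c("SPL", "LPL", "CRC")
  out$venn_up <- apply(dir_mat, 1L, .venn_cell, direction = "up")
  out$venn_down <- apply(dir_mat, 1L, .venn_cell, direction = "down")
  out
}

#' Two-cluster diagnostic for a pathway's expression signature
#'
#' Restricts the expression matrix to a pathway's genes, clusters the
#' samples hierarchically (Euclidean distance, Ward
#' minimum-within-cluster-variance linkage — the "inner squared
#' distance" criterion), cuts the tree into two clusters, and counts how
#' many samples the 2-cluster split misclassifies against the true
#' normal/tumor labels, minimized over the two possible
#' cluster-to-label assignments. A pathway whose dysregulation cleanly
#' separates tumors from normals gives a low count; at most floor(S/2)
#' is possible after minimization.
#'
#' @param expr Expression matrix already restricted to the pathway's
#'   genes (at least 2).
#' @param labels 0/1 phenotype vector for the columns.
#' @return List: `assignment` (cluster per sample, 0/1 in the
#'   label-matched orientation), `misclassified` (count), `tree` (the
#'   `hclust` object).
#' @export
cluster_diagnostic <- function(expr, labels) {
  if (nrow(expr) < 2L) stop("pathway must have at least 2 genes on the array")
  if (ncol(expr) < 3L) stop("need at least 3 samples to cluster")
  stopifnot(length(labels) == ncol(expr))
  tree <- stats::hclust(stats::dist(t(expr), method = "euclidean"),
                        method = "ward.D2")
  cl <- stats::cutree(tree, k = 2L) - 1L
  mis_direct <- sum(cl != labels)
  mis_flip <- sum((1L - cl) != labels)
  if (mis_flip < mis_direct) cl <- 1L - cl
  list(assignment = cl, misclassified = min(mis_direct, mis_flip),
       tree = tree)
}

#' PCA projection of samples on a gene signature
#'
#' Gene-centered principal component analysis of the samples restricted
#' to a gene list; returns the coordinates of each sample on the first
#' two components and the fraction of variance each component explains.
#' Centering is per gene, so the projection is invariant to per-gene
#' mean shifts.
#'
#' @param expr Expression matrix restricted to the signature genes
#'   (>= 2 genes, >= 3 samples).
#' @return List: `coords` (samples x 2 matrix, columns PC1/PC2),
#'   `explained` (variance fractions of all components, non-increasing).
#' @export
pca_projection <- function(expr) {
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (all(apply(expr, 1L, stats::var) == 0)) {
    stop("constant expression matrix: PCA undefined")
  }
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  list(coords = coords, explained = explained)
}
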