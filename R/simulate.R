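#' Configuration for a simulated two-group expression study
#'
#' Defaults mirror the design the enrichment pipeline targets: a
#' log2-scale array of G genes over a balanced normal/tumor cohort, with
#' gene sets of heterogeneous sizes like those of curated canonical
#' pathway collections (members sampled without replacement from the
#' array), Gaussian noise, and optionally some sets "planted" with a
#' mean shift in the tumor class.
#'
#' @param G Number of genes (default 2000).
#' @param n_normal,n_tumor Samples per class (default 30 each).
#' @param n_sets Number of gene sets (default 50).
#' @param set_size_range Inclusive range of set sizes; sizes are drawn
#'   uniformly. Default c(8, 400), the span typical of canonical-pathway
#'   collections.
#' @param planted List of plantings, each a list with `set` (index into
#'   the sets), `direction` (`"up"` or `"down"`), `delta` (effect size in
#'   units of `noise_sd`, >= 0) and `f` (fraction of members shifted,
#'   in (0, 1\]).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale
#'   (default 1).
#' @param baseline_range Per-gene baseline means are drawn uniformly
#'   from this range; default c(4, 12), mimicking log2 array
#'   intensities (the choice is cosmetic — the analysis is
#'   location-invariant per gene).
#' @param rho Optional equicorrelation of expression noise among a set's
#'   members (default 0 = independent genes). Useful for demonstrating
#'   that permutation p-values stay valid under correlation while the
#'   analytic Gaussian p does not.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(G = 2000L, n_normal = 30L, n_tumor = 30L,
                       n_sets = 50L, set_size_range = c(8L, 400L),
                       planted = list(), noise_sd = 1, rho = 0,
                       baseline_range = c(4, 12), seed = 1L) {
  stopifnot(G >= 2L, n_normal >= 2L, n_tumor >= 2L, n_sets >= 1L,
            noise_sd > 0, rho >= 0, rho < 1,
            set_size_range[[1L]] >= 1L, set_size_range[[2L]] <= G)
  for (pl in planted) {
    stopifnot(is.list(pl),
              pl$direction %in% c("up", "down"),
              pl$delta >= 0, pl$f > 0, pl$f <= 1)
    if (pl$set < 1L || pl$set > n_sets) {
      stop("planted set index out of range: ", pl$set)
    }
  }
  structure(list(G = as.integer(G), n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor), n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 planted = planted, noise_sd = noise_sd, rho = rho,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an expression study with known planted enrichment
#'
#' Draws per-gene baselines uniformly on the configured log2 range, adds
#' Gaussian noise of the configured standard deviation, and — for each
#' planted set — shifts the tumor-class mean of a fraction `f` of that
#' set's members by `delta * noise_sd` in the planted direction. Genes
#' shifted by more than one planting accumulate the shifts. With
#' `rho > 0`, members of a set share an equicorrelated latent factor (a
#' gene in several sets follows the first set that lists it).
#' Reproducible: the same configuration (including seed) always yields
#' identical output.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (matrix), `labels` (0/1 vector),
#'   `sets` (named list), and `truth`, itself a list with
#'   `set_direction` (named `"up"`/`"down"`/`"none"`) and `gene_shift`
#'   (named numeric, the true tumor-mean shift per gene).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, function() .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  G <- cfg$G
  S <- cfg$n_normal + cfg$n_tumor
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
                  sprintf("T%03d", seq_len(cfg$n_tumor)))
  labels <- phenotype_labels(rep(c(0L, 1L), c(cfg$n_normal, cfg$n_tumor)),
                             sample_ids = sample_ids)

  lo <- cfg$set_size_range[[1L]]; hi <- cfg$set_size_range[[2L]]
  sizes <- lo + sample.int(hi - lo + 1L, cfg$n_sets, replace = TRUE) - 1L
  sets <- lapply(sizes, function(k) sample(gene_ids, k))
  names(sets) <- sprintf("set%03d", seq_len(cfg$n_sets))

  gene_shift <- stats::setNames(numeric(G), gene_ids)
  set_direction <- stats::setNames(rep("none", cfg$n_sets), names(sets))
  for (pl in cfg$planted) {
    if (pl$delta == 0) next
    members <- sets[[pl$set]]
    n_shift <- ceiling(pl$f * length(members))
    chosen <- sample(members, n_shift)
    sgn <- if (pl$direction == "up") 1 else -1
    gene_shift[chosen] <- gene_shift[chosen] + sgn * pl$delta * cfg$noise_sd
    set_direction[[pl$set]] <- pl$direction
  }

  baseline <- stats::runif(G, cfg$baseline_range[[1L]],
                           cfg$baseline_range[[2L]])
  expr <- matrix(stats::rnorm(G * S, sd = cfg$noise_sd), G, S,
                 dimnames = list(gene_ids, sample_ids))
  if (cfg$rho > 0) {
    # shared latent factor per set -> equicorrelated members
    first_set <- integer(G)
    for (j in seq_along(sets)) {
      idx <- match(sets[[j]], gene_ids)
      idx <- idx[first_set[idx] == 0L]
      first_set[idx] <- j
    }
    factors <- matrix(stats::rnorm(length(sets) * S), length(sets), S)
    in_set <- first_set > 0L
    expr[in_set, ] <- sqrt(1 - cfg$rho) * expr[in_set, ] +
      sqrt(cfg$rho) * cfg$noise_sd * factors[first_set[in_set], ]
  }
  expr <- expr + baseline
  tumor_cols <- which(labels == 1L)
  expr[, tumor_cols] <- expr[, tumor_cols] + gene_shift

  list(expr = validate_expression(expr), labels = labels, sets = sets,
       truth = list(set_direction = set_direction, gene_shift = gene_shift))
}

#' Write a simulated dataset to GCT + CLS + GMT + ground-truth TSV
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sim").
#' @return Named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expr = file.path(dir, paste0(prefix, ".gct")),
    cls = file.path(dir, paste0(prefix, ".cls")),
    gmt = file.path(dir, paste0(prefix, ".gmt")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_expression(sim$expr, paths[["expr"]], format = "gct")
  write_cls(sim$labels, paths[["cls"]])
  write_gmt(sim$sets, paths[["gmt"]])
  truth <- data.frame(set = names(sim$truth$set_direction),
                      direction = sim$truth$set_direction)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Reference stage-wise pathway enrichment tables for colorectal
#' tumorigenesis
#'
#' Returns the published per-stage enrichment calls for canonical
#' pathways across three stages of colorectal tumorigenesis — small
#' preinvasive lesions (SPL), large preinvasive lesions (LPL), and
#' invasive carcinomas (CRC), each contrasted against normal mucosa —
#' transcribed verbatim from the printed tables and bundled as
#' plain-text data. One table lists pathways significantly upregulated
#' in tumors at one or more stages, the other pathways downregulated;
#' cells hold nominal permutation p-values (NA where the pathway was not
#' significant at that stage), and `n` is the pathway's effective size
#' in RefSeq identifiers.
#'
#' These tables anchor the reporting layer: Venn/trajectory counts and
#' the up-versus-down set-size comparison are recomputed from them in
#' the package tests.
#'
#' @return List with data frames `up` and `down`, each with columns
#'   `pathway`, `n`, `p_SPL`, `p_LPL`, `p_CRC`.
#' @export
crc_stage_tables <- function() {
  dir <- system.file("extdata", package = "rsstages")
  list(up = read_result_table(file.path(dir, "crc_stage_up.tsv")),
       down = read_result_table(file.path(dir, "crc_stage_down.tsv")))
}
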