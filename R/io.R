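#' Read an expression matrix from a GCT or TSV file
#'
#' Reads a genes-by-samples matrix of log-scale intensities. The GCT 1.2
#' dialect is the standard one: a `#1.2` version line, a dimensions line,
#' then a header with `Name` and `Description` columns followed by one
#' column per sample. The TSV dialect is a plain table whose first column
#' holds gene identifiers and whose remaining columns are samples.
#'
#' @param path Path to the file.
#' @param format Either `"gct"` or `"tsv"`. Defaults to guessing from the
#'   file extension (`.gct` means GCT, anything else TSV).
#' @return A validated numeric matrix with gene identifiers as row names
#'   and sample identifiers as column names.
#' @seealso [write_expression()], [validate_expression()]
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || trimws(lines[[1L]]) != "#1.2") {
      stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    }
    dims <- as.integer(strsplit(trimws(lines[[2L]]), "\t")[[1L]])
    tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                             check.names = FALSE, colClasses = "character")
    if (!identical(tolower(names(tab)[1:2]), c("name", "description"))) {
      stop("GCT header must start with Name and Description columns")
    }
    gene_ids <- tab[[1L]]
    values <- tab[, -(1:2), drop = FALSE]
    if (nrow(tab) != dims[[1L]] || ncol(values) != dims[[2L]]) {
      stop(sprintf("GCT dimensions line says %d x %d but body is %d x %d",
                   dims[[1L]], dims[[2L]], nrow(tab), ncol(values)))
    }
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    gene_ids <- tab[[1L]]
    values <- tab[, -1L, drop = FALSE]
  }
  mat <- .parse_numeric_cells(values, gene_ids, path)
  rownames(mat) <- gene_ids
  validate_expression(mat)
}

# character data.frame -> numeric matrix with coordinates in error messages
.parse_numeric_cells <- function(values, gene_ids, path) {
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(values)), nrow = length(gene_ids),
           dimnames = list(NULL, colnames(values)))
  )
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s', sample '%s' in %s",
      gene_ids[[i]], colnames(values)[[j]], path))
  }
  mat
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream operation assumes: a numeric
#' matrix with at least 2 genes and 4 samples, unique gene and sample
#' identifiers, and no missing or non-finite values.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly unchanged, for piping.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene row names and sample column names")
  }
  dup <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup) > 0L) {
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample identifiers")
  }
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-finite value at gene '%s', sample '%s'",
                 rownames(expr)[bad[[1L]]], colnames(expr)[bad[[2L]]]))
  }
  invisible(expr)
}

#' Write an expression matrix to GCT or TSV
#'
#' @inheritParams read_expression
#' @param expr Numeric matrix with gene row names and sample column names.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "gct", "tsv")) {
  validate_expression(expr)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  # format(..., digits = 17) keeps doubles bit-exact on round trip
  body <- cbind(data.frame(Name = rownames(expr),
                           Description = rep("na", nrow(expr)),
                           check.names = FALSE),
                as.data.frame(format(expr, digits = 17, trim = TRUE,
                                     scientific = FALSE)))
  if (format == "gct") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(body[, -2L], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read phenotype labels from a CLS file
#'
#' CLS is the positional companion format of GCT: a header line
#' `<S> 2 1`, a class-name line starting with `#`, and a line of S labels
#' (either the class names themselves or 0/1 codes in class-name order).
#' Labels are recoded so that the class representing normal mucosa maps
#' to 0 and the tumor class to 1: a class literally named `N`, `NORMAL`
#' or `0` is taken as the normal class; otherwise the first-listed class
#' is 0, the usual CLS convention.
#'
#' @param path Path to the CLS file.
#' @param stage Optional stage tag for the tumor class, one of `"SPL"`,
#'   `"LPL"`, `"CRC"`; stored as the `stage` attribute.
#' @return Integer vector of 0/1 labels with attributes `class_names`
#'   (names in 0/1 order) and `stage`.
#' @export
read_cls <- function(path, stage = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("CLS file must have 3 lines: ", path)
  hdr <- as.integer(strsplit(lines[[1L]], "[ \t]+")[[1L]])
  n_samples <- hdr[[1L]]; n_classes <- hdr[[2L]]
  if (is.na(n_classes) || n_classes != 2L) {
    stop("CLS must declare exactly 2 classes, found: ", n_classes)
  }
  cls_line <- sub("^#[ \t]*", "", lines[[2L]])
  class_names <- strsplit(cls_line, "[ \t]+")[[1L]]
  if (length(class_names) != 2L) {
    stop("CLS class-name line must name 2 classes")
  }
  tokens <- strsplit(lines[[3L]], "[ \t]+")[[1L]]
  if (length(tokens) != n_samples) {
    stop(sprintf("CLS header declares %d samples but %d labels were found",
                 n_samples, length(tokens)))
  }
  normal_idx <- which(toupper(class_names) %in% c("N", "NORMAL", "0"))
  if (length(normal_idx) != 1L) normal_idx <- 1L
  ordered_names <- c(class_names[normal_idx], class_names[-normal_idx])
  if (all(tokens %in% class_names)) {
    labels <- as.integer(tokens == ordered_names[[2L]])
  } else if (all(tokens %in% c("0", "1"))) {
    # numeric tokens index classes in the order of the class-name line
    labels <- as.integer(class_names[as.integer(tokens) + 1L] ==
                           ordered_names[[2L]])
  } else {
    stop("CLS labels must be class names or 0/1 codes")
  }
  phenotype_labels(labels, stage = stage, class_names = ordered_names)
}

#' Construct a phenotype-label vector
#'
#' @param labels Vector coercible to 0/1 integers; 0 = normal, 1 = tumor.
#' @param sample_ids Optional sample identifiers, stored as names.
#' @param stage Optional tumor-stage tag (`"SPL"`, `"LPL"` or `"CRC"`).
#' @param class_names Optional character pair naming classes 0 and 1.
#' @return Integer 0/1 vector with optional names and attributes.
#' @export
phenotype_labels <- function(labels, sample_ids = NULL, stage = NULL,
                             class_names = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (normal) or 1 (tumor)")
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L) {
    stop("each class needs at least 2 samples")
  }
  if (!is.null(sample_ids)) {
    stopifnot(length(sample_ids) == length(labels))
    names(labels) <- sample_ids
  }
  if (!is.null(stage)) {
    stage <- match.arg(stage, c("SPL", "LPL", "CRC"))
    attr(labels, "stage") <- stage
  }
  if (!is.null(class_names)) attr(labels, "class_names") <- class_names
  labels
}

#' Check that labels align with an expression matrix
#'
#' Labels carrying sample names must match the matrix columns exactly and
#' in the same order; unnamed labels are checked by length only (CLS files
#' are positional).
#'
#' @param labels 0/1 vector from [read_cls()] or [phenotype_labels()].
#' @param expr Expression matrix.
#' @return `labels`, invisibly.
#' @export
validate_labels <- function(labels, expr) {
  if (length(labels) != ncol(expr)) {
    stop(sprintf("%d labels for %d samples", length(labels), ncol(expr)))
  }
  if (!is.null(names(labels)) &&
      !identical(unname(names(labels)), unname(colnames(expr)))) {
    stop("label sample ids do not match the expression matrix order")
  }
  invisible(labels)
}

#' Write phenotype labels to a CLS file
#'
#' @param labels 0/1 vector; class 0 is written first.
#' @param path Output path.
#' @param class_names Character pair naming classes 0 and 1.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- attr(labels, "class_names")
    if (is.null(class_names)) class_names <- c("N", "T")
  }
  writeLines(c(paste(length(labels), 2, 1),
               paste("#", class_names[[1L]], class_names[[2L]]),
               paste(class_names[as.integer(labels) + 1L], collapse = " ")),
             path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per tab-separated line: name, description (kept as an
#' attribute), then member identifiers. Members are de-duplicated within
#' each set; a message reports how many duplicates were dropped. Lines
#' with no members are skipped with a warning; duplicate set names are an
#' error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors, with a `descriptions`
#'   attribute parallel to the names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1L)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup) > 0L) {
    stop("duplicate gene-set names in GMT: ", paste(dup, collapse = ", "))
  }
  empty <- lengths(parts) < 3L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no members skipped: ",
            paste(names_[empty], collapse = ", "))
    parts <- parts[!empty]
    names_ <- names_[!empty]
  }
  descriptions <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  n_dup <- sum(lengths(parts) - 2L) - sum(lengths(sets))
  if (n_dup > 0L) {
    message(n_dup, " duplicate member(s) dropped across sets")
  }
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(descriptions, names_)
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Effective set sizes on an array
#'
#' The effective size n of a gene set is the number of its distinct
#' members present among the array's gene identifiers (exact string
#' match); n is what enters every null-moment formula.
#'
#' @param sets Named list of character vectors.
#' @param expr Expression matrix (its row names define the array).
#' @return Named integer vector of effective sizes.
#' @export
effective_sizes <- function(sets, expr) {
  genes <- rownames(expr)
  vapply(sets, function(s) sum(unique(s) %in% genes), integer(1))
}

#' Write a per-stage enrichment result table
#'
#' One row per pathway with its effective size, per-stage nominal
#' p-values and direction calls. Cells for stages where the pathway was
#' not significant are rendered `-`, matching the conventional printed
#' layout. Rows are ordered by the first stage at which the pathway is
#' significant, then by the p-value at that stage (stable sort).
#'
#' @param results Data frame with columns `pathway`, `n`, `p_SPL`,
#'   `p_LPL`, `p_CRC` (NA where not significant) and optionally
#'   `dir_SPL`, `dir_LPL`, `dir_CRC`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_result_table()]
#' @export
write_result_table <- function(results, path) {
  stage_cols <- c("p_SPL", "p_LPL", "p_CRC")
  stopifnot(all(c("pathway", "n") %in% names(results)))
  for (col in stage_cols) if (!col %in% names(results)) results[[col]] <- NA_real_
  if (nrow(results) > 0L) {
    pmat <- as.matrix(results[, stage_cols])
    first_sig <- apply(pmat, 1L, function(p) {
      i <- which(!is.na(p)); if (length(i) == 0L) Inf else i[[1L]]
    })
    first_p <- vapply(seq_len(nrow(pmat)), function(i) {
      if (is.finite(first_sig[[i]])) pmat[i, first_sig[[i]]] else Inf
    }, numeric(1))
    results <- results[order(first_sig, first_p), , drop = FALSE]
  }
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "-",
                           format(out[[col]], digits = 15, trim = TRUE,
                                  scientific = FALSE))
    } else {
      out[[col]] <- ifelse(is.na(out[[col]]), "-", as.character(out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame with `-` cells restored to NA and numeric columns
#'   re-typed.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  tab[tab == "-"] <- NA
  for (col in c("n", "p_SPL", "p_LPL", "p_CRC")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("n" %in% names(tab)) tab[["n"]] <- as.integer(tab[["n"]])
  tab
}
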