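# Expression matrices are plain numeric matrices: rows = genes, columns =
# samples, dimnames carry the identifiers. Identifiers are opaque strings.

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique, non-empty gene rownames and sample colnames, all
#' values finite, at least 2 genes and 1 sample.
#'
#' @param x numeric matrix, genes x samples, with dimnames.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (ncol(x) < 1L) stop("need at least 1 sample")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'")
  }
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' The file must have a header row of sample identifiers and gene
#' identifiers in the first column (the usual gene-major layout of GEO
#' series exports). Use `transpose = TRUE` for sample-major files.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param transpose logical; if `TRUE` the file is samples x genes and is
#'   transposed after reading.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv"), transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an id column plus data")
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value at row '", ids[bad[1L, 1L]], "', column '",
         colnames(vals)[bad[1L, 2L]], "': \"",
         as.matrix(vals)[bad[1L, , drop = FALSE]], "\"")
  }
  if (anyNA(num) || !all(is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1L, ]
    stop("missing or non-finite value at row '", ids[bad[1L]],
         "', column '", colnames(vals)[bad[2L]], "'")
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (transpose) num <- t(num)
  check_expression(num)
  num
}

#' Write an expression matrix to a delimited text file
#'
#' @inheritParams read_expression
#' @param x numeric matrix, genes x samples.
#' @param id_column header for the gene id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "csv"),
                             id_column = "gene_id") {
  dialect <- match.arg(dialect)
  check_expression(x)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level measurements to gene level
#'
#' Probes mapping to exactly one gene are kept; the per-sample measurements
#' of multiple probes for the same gene are averaged; probes mapping to no
#' gene or to more than one gene are dropped. A probe's missing value in a
#' sample is excluded from that sample's average (pairwise deletion) — pass
#' `NA`s only through this function, downstream code requires finite values.
#'
#' @param x numeric matrix, probes x samples (NA allowed).
#' @param map data.frame with columns `probe_id` and `gene_id`; a probe
#'   appearing in several rows maps to several genes (and is dropped).
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(x, map) {
  if (!is.matrix(x) || is.null(rownames(x)))
    stop("probe matrix must have probe rownames")
  if (!all(c("probe_id", "gene_id") %in% colnames(map)))
    stop("map must have columns probe_id and gene_id")
  map <- map[map$probe_id %in% rownames(x), , drop = FALSE]
  n_genes <- tapply(map$gene_id, map$probe_id, function(g) length(unique(g)))
  keep_probes <- names(n_genes)[n_genes == 1L]
  map <- map[map$probe_id %in% keep_probes, , drop = FALSE]
  map <- map[!duplicated(map$probe_id), , drop = FALSE]
  if (nrow(map) == 0L) stop("no probes map uniquely to a gene")
  sub <- x[map$probe_id, , drop = FALSE]
  gene <- factor(map$gene_id, levels = unique(map$gene_id))
  out <- apply(sub, 2L, function(col) {
    tapply(col, gene, function(v) mean(v, na.rm = TRUE))
  })
  out <- matrix(out, nrow = nlevels(gene),
                dimnames = list(levels(gene), colnames(x)))
  if (nrow(out) < 2L)
    stop("fewer than 2 genes after collapsing probes")
  check_expression(out)
  out
}

#' Read / write TFP-TFN sample labels
#'
#' Labels files are two-column delimited text (sample id, label); the only
#' accepted labels are `"TFP"` and `"TFN"`.
#'
#' @param path path to the file.
#' @param header logical; does the file carry a header row?
#' @return named character vector of `"TFP"`/`"TFN"`, names = sample ids.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = header, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file must have two columns")
  labs <- df[[2L]]
  bad <- setdiff(unique(labs), c("TFP", "TFN"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected TFP or TFN)")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample ids in labels file")
  stats::setNames(labs, df[[1L]])
}

#' @rdname read_labels
#' @param labels named character vector of `"TFP"`/`"TFN"`.
#' @export
write_labels <- function(labels, path) {
  check_labels(labels)
  utils::write.table(data.frame(names(labels), unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_labels <- function(labels, x = NULL, require_both = FALSE) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("labels must be a named vector (names = sample ids)")
  bad <- setdiff(unique(labels), c("TFP", "TFN"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (!is.null(x)) {
    missing <- setdiff(names(labels), colnames(x))
    if (length(missing))
      stop("labelled samples absent from matrix: ",
           paste(missing, collapse = ", "))
  }
  if (require_both && length(unique(labels)) < 2L)
    stop("both TFP and TFN labels are required")
  invisible(labels)
}
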