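# Single-cell fusion calls by repeated pseudobulk voting. From the N
# tumor cells of one sample, N pseudobulks are built (the per-gene mean
# of a random n-cell subset, n = 1..N, drawn without replacement); each
# pseudobulk is classified by the signature and the TFP-call count is
# tested against a fair coin with an exact two-sided binomial test.

#' Read a single-cell count matrix (MatrixMarket triplet)
#'
#' Reads the standard `.mtx` + features + barcodes trio (uncompressed
#' text). The feature file's first column provides gene ids; the barcode
#' file one barcode per line.
#'
#' @param mtx_path MatrixMarket file, genes x cells.
#' @param features_path one feature per line (first tab-separated column
#'   used as gene id).
#' @param barcodes_path one cell barcode per line.
#' @param tumor_flags optional named logical vector (names = barcodes) or
#'   path to a two-column TSV (barcode, 0/1) marking tumor cells.
#' @return list of class `"cell_matrix"`: `counts` (sparse genes x cells),
#'   `gene_ids`, `cell_ids`, `tumor` (logical per cell).
#' @export
read_cell_matrix <- function(mtx_path, features_path, barcodes_path,
                             tumor_flags = NULL) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("no such file: ", p)
  counts <- Matrix::readMM(mtx_path)
  genes <- vapply(strsplit(readLines(features_path), "\t"), `[[`, "", 1L)
  cells <- readLines(barcodes_path)
  if (length(genes) != nrow(counts) || length(cells) != ncol(counts))
    stop("feature/barcode counts do not match matrix dimensions")
  if (anyDuplicated(genes)) stop("duplicate gene ids in features file")
  dimnames(counts) <- list(genes, cells)
  tumor <- rep(TRUE, length(cells))
  if (!is.null(tumor_flags)) {
    if (is.character(tumor_flags) && length(tumor_flags) == 1L) {
      df <- utils::read.table(tumor_flags, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
      tumor_flags <- stats::setNames(as.logical(as.integer(df[[2L]])),
                                     df[[1L]])
    }
    if (is.null(names(tumor_flags)))
      stop("tumor flags must be named by cell barcode")
    tumor <- unname(tumor_flags[cells])
    if (anyNA(tumor)) stop("tumor flag missing for some barcodes")
  }
  structure(list(counts = counts, gene_ids = genes, cell_ids = cells,
                 tumor = tumor),
            class = "cell_matrix")
}

#' Build the ladder of random pseudobulks from one sample's tumor cells
#'
#' For N tumor cells, pseudobulk n (n = 1..N) is the per-gene mean of a
#' uniform random subset of n tumor cells drawn without replacement;
#' pseudobulk N is therefore the mean over all tumor cells.
#'
#' @param cm a `"cell_matrix"`, or a counts matrix (genes x cells) with
#'   `tumor` supplied separately.
#' @param seed integer seed; subsets are reproducible.
#' @param tumor logical per-cell vector when `cm` is a bare matrix.
#' @param cpm normalize each cell to counts-per-million before averaging?
#' @return numeric matrix, genes x N pseudobulks (columns `pb0001`...);
#'   the sampled cell subsets are attached as attribute `"subsets"`.
#' @export
make_pseudobulks <- function(cm, seed = 1L, tumor = NULL, cpm = FALSE) {
  if (inherits(cm, "cell_matrix")) {
    counts <- cm$counts; tumor <- cm$tumor
  } else {
    counts <- cm
    if (is.null(tumor)) tumor <- rep(TRUE, ncol(counts))
  }
  idx <- which(tumor)
  n_t <- length(idx)
  if (n_t < 1L) stop("no tumor cells: cannot build pseudobulks")
  counts <- as.matrix(counts)
  if (cpm) {
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    counts <- sweep(counts, 2L, tot, "/") * 1e6
  }
  set.seed(as.integer(seed))
  subsets <- lapply(seq_len(n_t), function(n) sample(idx, n))
  pb <- vapply(subsets, function(s) {
    rowMeans(counts[, s, drop = FALSE])
  }, numeric(nrow(counts)))
  pb <- matrix(pb, nrow = nrow(counts))
  dimnames(pb) <- list(rownames(counts),
                       sprintf("pb%04d", seq_len(n_t)))
  attr(pb, "subsets") <- subsets
  pb
}

#' Exact binomial call from a TFP-vote count
#'
#' Two-sided exact binomial test of `n_tfp` successes in `n_total` trials
#' against p = 0.5. The call is TFP when significant with a TFP majority,
#' TFN when significant with a TFN majority, otherwise indeterminate.
#'
#' @param n_tfp number of pseudobulks called TFP.
#' @param n_total number of pseudobulks.
#' @param alpha significance level.
#' @return list: `p_value`, `call` in `{"TFP","TFN","indeterminate"}`.
#' @export
binomial_call <- function(n_tfp, n_total, alpha = 0.05) {
  if (n_total < 1L || n_tfp < 0L || n_tfp > n_total)
    stop("need 0 <= n_tfp <= n_total, n_total >= 1")
  p <- stats::binom.test(n_tfp, n_total, p = 0.5)$p.value
  call <- if (p >= alpha) "indeterminate"
          else if (n_tfp > n_total / 2) "TFP"
          else "TFN"
  list(p_value = p, call = call)
}

#' Call one single-cell sample's fusion status by pseudobulk voting
#'
#' @param cm a `"cell_matrix"` (or bare counts matrix with `tumor`).
#' @param sig a `"t2e_signature"`.
#' @param seed integer seed for the pseudobulk subsets.
#' @param alpha significance level of the binomial test.
#' @param sample_id label for the output row.
#' @inheritParams make_pseudobulks
#' @return one-row data.frame: `sample_id`, `n_pseudobulks`,
#'   `n_tfp_calls`, `p_value`, `call`.
#' @export
vote_sample <- function(cm, sig, seed = 1L, alpha = 0.05,
                        sample_id = "sample", tumor = NULL, cpm = FALSE) {
  pb <- make_pseudobulks(cm, seed = seed, tumor = tumor, cpm = cpm)
  res <- classify_samples(pb, sig)
  n_tfp <- sum(res$predicted == "TFP")
  bc <- binomial_call(n_tfp, ncol(pb), alpha = alpha)
  data.frame(sample_id = sample_id, n_pseudobulks = ncol(pb),
             n_tfp_calls = n_tfp, p_value = bc$p_value, call = bc$call,
             row.names = NULL, stringsAsFactors = FALSE)
}
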