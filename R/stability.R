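# Five per-gene variability metrics and their rank-aggregation fusion.
# Smaller metric = more stable expression. The fused score is the mean of
# the five ascending metric ranks; the bottom quartile of fused scores is
# the "stable" stratum (SEGs), the top quartile "unstable" (USEGs), and
# together they form the reference genes paired with the anchor.

F_SENTINEL <- 1e12  # returned when within-group variance is exactly zero
                    # but the group means differ; keeps the metric finite

#' One-way ANOVA F-statistic between TFP and TFN groups
#'
#' Degenerate case: if the pooled within-group variance is exactly zero
#' the statistic is 0 when the group means are equal and a large finite
#' sentinel (`1e12`) otherwise.
#'
#' @param values numeric vector, one value per sample.
#' @param labels TFP/TFN vector aligned with `values` (or named by the
#'   same sample ids when `values` is named).
#' @return nonnegative scalar.
#' @export
f_statistic <- function(values, labels) {
  labels <- align_labels(values, labels)
  g1 <- values[labels == "TFN"]; g2 <- values[labels == "TFP"]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 samples for the F-statistic")
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  if (ssw == 0) {
    return(if (mean(g1) == mean(g2)) 0 else F_SENTINEL)
  }
  unname(stats::oneway.test(values ~ factor(labels),
                            var.equal = TRUE)$statistic)
}

#' Shannon entropy of discretized expression
#'
#' Values are binned into `bins` equal-width intervals spanning
#' `[min, max]`; entropy is `-sum(p * log2(p))` over occupied bins, in
#' bits. A constant vector has entropy 0.
#'
#' @param values numeric vector.
#' @param bins number of bins (>= 2).
#' @return nonnegative scalar (bits).
#' @export
shannon_entropy <- function(values, bins = 10L) {
  if (bins < 2L) stop("bins must be >= 2")
  rng <- range(values)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  counts <- tabulate(cut(values, breaks, include.lowest = TRUE,
                         labels = FALSE), nbins = bins)
  p <- counts[counts > 0L] / length(values)
  -sum(p * log2(p))
}

#' Coefficient of variation
#'
#' Population (n-denominator) standard deviation over the mean. Defined
#' as 0 for a zero mean (expression is nonnegative, so this only occurs
#' for an all-zero gene).
#'
#' @param values numeric vector.
#' @return nonnegative scalar.
#' @export
coefficient_of_variation <- function(values) {
  mu <- mean(values)
  if (mu == 0) return(0)
  sqrt(mean((values - mu)^2)) / mu
}

#' Outlier-sum statistic
#'
#' Flags values outside `[Q1 - coef*IQR, Q3 + coef*IQR]` (quartiles by
#' the type-7 quantile rule) and returns the sum of their absolute
#' median-centered deviations; 0 when nothing is flagged. The default
#' `coef = 1` is deliberately tighter than the conventional 1.5.
#'
#' @param values numeric vector, length >= 4.
#' @param coef IQR multiplier for the outlier fences.
#' @return nonnegative scalar.
#' @export
outlier_sum <- function(values, coef = 1) {
  if (length(values) < 4L) stop("outlier_sum needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  flagged <- values < q[1L] - coef * iqr | values > q[2L] + coef * iqr
  if (!any(flagged)) return(0)
  sum(abs(values[flagged] - stats::median(values)))
}

#' Median absolute deviation (raw, no consistency constant)
#'
#' @param values numeric vector.
#' @return nonnegative scalar: `median(|x - median(x)|)`.
#' @export
median_absolute_deviation <- function(values) {
  stats::mad(values, constant = 1)
}

#' Score every gene with the five variability metrics
#'
#' @param x numeric matrix, genes x samples.
#' @param labels named TFP/TFN vector covering the columns of `x` that
#'   enter the F-statistic; all five metrics are computed on the labelled
#'   samples only, so the table is label-consistent.
#' @param bins entropy bin count.
#' @param outlier_coef IQR multiplier for [outlier_sum()].
#' @return data.frame: gene_id, f_stat, entropy, cv, outlier_sum, mad.
#' @export
gene_stability <- function(x, labels, bins = 10L, outlier_coef = 1) {
  check_expression(x)
  check_labels(labels, x, require_both = TRUE)
  x <- x[, names(labels), drop = FALSE]
  lab <- unname(labels)
  data.frame(
    gene_id = rownames(x),
    f_stat = apply(x, 1L, f_statistic, labels = lab),
    entropy = apply(x, 1L, shannon_entropy, bins = bins),
    cv = apply(x, 1L, coefficient_of_variation),
    outlier_sum = apply(x, 1L, outlier_sum, coef = outlier_coef),
    mad = apply(x, 1L, median_absolute_deviation),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fuse the five metrics and select reference genes
#'
#' Each metric is converted to an ascending rank (ties averaged; smaller
#' metric = more stable); the fused score is the mean of the five ranks.
#' The bottom quartile of fused scores is labelled `stable`, the top
#' quartile `unstable`, everything else `neither`; exactly
#' `floor(quartile * n)` genes land in each selected stratum. The anchor
#' gene is excluded before ranking. Boundary ties are broken by gene id.
#'
#' @param scores data.frame from [gene_stability()].
#' @param quartile selected fraction at each extreme (default 0.25).
#' @param anchor anchor gene id to exclude (default `"ERG"`).
#' @return `scores` (anchor dropped) with columns `fused_score` and
#'   `category`, ordered from most stable to most variable.
#' @export
fuse_and_select <- function(scores, quartile = 0.25, anchor = "ERG") {
  metrics <- c("f_stat", "entropy", "cv", "outlier_sum", "mad")
  if (!all(c("gene_id", metrics) %in% colnames(scores)))
    stop("scores must come from gene_stability()")
  scores <- scores[scores$gene_id != anchor, , drop = FALSE]
  n <- nrow(scores)
  if (n < 8L) stop("need at least 8 genes to take quartiles")
  if (quartile <= 0 || quartile > 0.5) stop("quartile must be in (0, 0.5]")
  rank_mat <- vapply(scores[metrics], rank, numeric(n),
                     ties.method = "average")
  scores$fused_score <- rowMeans(rank_mat)
  ord <- order(scores$fused_score, scores$gene_id)
  scores <- scores[ord, , drop = FALSE]
  n_sel <- floor(quartile * n)
  category <- rep("neither", n)
  if (n_sel > 0L) {
    category[seq_len(n_sel)] <- "stable"
    category[seq.int(n - n_sel + 1L, n)] <- "unstable"
  }
  scores$category <- category
  rownames(scores) <- NULL
  scores
}

#' Reference genes from a fused stability table
#'
#' @param fused output of [fuse_and_select()].
#' @return character vector of stable + unstable gene ids.
#' @export
reference_genes <- function(fused) {
  fused$gene_id[fused$category != "neither"]
}

# align a label vector with a values vector (by names when available)
align_labels <- function(values, labels) {
  if (!is.null(names(labels)) && !is.null(names(values)))
    labels <- labels[names(values)]
  if (length(labels) != length(values))
    stop("labels and values lengths differ")
  bad <- setdiff(unique(labels), c("TFP", "TFN"))
  if (length(bad) || anyNA(labels))
    stop("labels must be TFP or TFN for every sample")
  unname(labels)
}
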