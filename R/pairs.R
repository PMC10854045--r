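# Pair screening on within-sample ranks: the reverse-degree statistic and
# the per-pair harmonic mean of sensitivity and specificity (the "paper
# F-1", not the precision-recall F1). Canonical ordering of scored pairs
# everywhere: F-1 descending, then reverse degree descending, then partner
# gene id — this fixes every tie deterministically.

#' Within-sample ranks of all genes
#'
#' Ranks each column (sample) in ascending order: 1 = lowest expression;
#' ties averaged. Ranks are invariant to any strictly increasing
#' per-sample transform of the matrix — the property that makes all
#' downstream statistics platform-free.
#'
#' @param x numeric matrix, genes x samples.
#' @return matrix of the same shape and dimnames holding the ranks.
#' @export
rank_within_samples <- function(x) {
  check_expression(x)
  r <- apply(x, 2L, rank)
  dimnames(r) <- dimnames(x)
  r
}

#' Reverse degree of an anchored gene pair
#'
#' The geometric mean of the two groups' normalized absolute summed rank
#' differences:
#' `sqrt(|sum_TFN(R_a - R_p)|/m * |sum_TFP(R_a - R_p)|/n)`.
#' Computed exactly as written: each group's per-sample rank differences
#' are summed first and the absolute value taken afterwards, so opposing
#' differences within a group cancel.
#'
#' @param ranks rank matrix from [rank_within_samples()].
#' @param labels named TFP/TFN vector over columns of `ranks`.
#' @param anchor,partner gene ids (rows of `ranks`).
#' @param signed if `TRUE`, return 0 unless the two groups' summed rank
#'   differences have opposite signs (a true reversal); the default
#'   `FALSE` keeps the statistic exactly as defined, which also rewards
#'   large same-direction rank gaps.
#' @return nonnegative scalar.
#' @export
reverse_degree <- function(ranks, labels, anchor = "ERG", partner,
                           signed = FALSE) {
  missing <- setdiff(c(anchor, partner), rownames(ranks))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  check_labels(labels)
  d <- ranks[anchor, names(labels)] - ranks[partner, names(labels)]
  tfn <- d[labels == "TFN"]; tfp <- d[labels == "TFP"]
  if (!length(tfn) || !length(tfp))
    stop("need at least one sample in each group")
  if (signed && sum(tfn) * sum(tfp) > 0) return(0)
  sqrt(abs(sum(tfn)) / length(tfn) * abs(sum(tfp)) / length(tfp))
}

#' Harmonic mean of sensitivity and specificity
#'
#' @param sen,spe values in `[0, 1]`.
#' @return `2*sen*spe/(sen+spe)`, or 0 when both are 0.
#' @export
harmonic_f1 <- function(sen, spe) {
  ifelse(sen + spe > 0, 2 * sen * spe / (sen + spe), 0)
}

#' Classification value of a single gene pair
#'
#' Each sample votes by the within-sample ordering of the two raw values.
#' Both orientations are evaluated — anchor > partner votes TFP
#' (`"gt"`), or anchor < partner votes TFP (`"lt"`) — and the one with
#' the larger F-1 is returned; an exact F-1 tie keeps the biological
#' default `"gt"` (fusion elevates the anchor). Ties
#' `E_anchor == E_partner` vote TFN under either orientation.
#'
#' @param x numeric matrix, genes x samples.
#' @param labels named TFP/TFN vector over columns of `x`.
#' @param anchor,partner gene ids.
#' @return list: `sensitivity`, `specificity`, `f1`, `direction`.
#' @export
pair_f1 <- function(x, labels, anchor = "ERG", partner) {
  missing <- setdiff(c(anchor, partner), rownames(x))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  check_labels(labels, require_both = TRUE)
  a <- x[anchor, names(labels)]; p <- x[partner, names(labels)]
  is_tfp <- labels == "TFP"
  eval_dir <- function(votes_tfp) {
    sen <- mean(votes_tfp[is_tfp])
    spe <- mean(!votes_tfp[!is_tfp])
    list(sensitivity = sen, specificity = spe, f1 = harmonic_f1(sen, spe))
  }
  gt <- eval_dir(a > p)
  lt <- eval_dir(a < p)
  if (lt$f1 > gt$f1) c(lt, direction = "lt") else c(gt, direction = "gt")
}

#' Score every anchored pair against a reference-gene set
#'
#' @param x numeric matrix, genes x samples.
#' @param labels named TFP/TFN vector.
#' @param refs character vector of reference (partner) gene ids.
#' @param anchor anchor gene id.
#' @return data.frame, one row per pair, in canonical order (F-1 desc,
#'   reverse degree desc, partner id): partner, direction,
#'   reverse_degree, sensitivity, specificity, f1.
#' @export
screen_pairs <- function(x, labels, refs, anchor = "ERG") {
  check_expression(x)
  check_labels(labels, x, require_both = TRUE)
  refs <- setdiff(unique(as.character(refs)), anchor)
  missing <- setdiff(c(anchor, refs), rownames(x))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (!length(refs)) stop("no reference genes to screen")
  ranks <- rank_within_samples(x)
  rows <- lapply(refs, function(g) {
    pf <- pair_f1(x, labels, anchor, g)
    data.frame(partner = g, direction = pf$direction,
               reverse_degree = reverse_degree(ranks, labels, anchor, g),
               sensitivity = pf$sensitivity, specificity = pf$specificity,
               f1 = pf$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$f1, -out$reverse_degree, out$partner), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the candidate pair pool
#'
#' The pool is the union of: the top `top_k` pairs by reverse degree, the
#' top `top_k` pairs by F-1, and the intersection of the top `top_frac`
#' fractions of both rankings (`ceiling(top_frac * n)` pairs each),
#' deduplicated. Within each ranking, ties fall back on the other
#' statistic and then the partner id.
#'
#' @param scores data.frame from [screen_pairs()].
#' @param top_frac fraction defining "high" reversal/discrimination.
#' @param top_k head size of each ranking.
#' @return subset of `scores` in canonical order.
#' @export
candidate_pool <- function(scores, top_frac = 0.20, top_k = 10L) {
  need <- c("partner", "reverse_degree", "f1")
  if (!all(need %in% colnames(scores)))
    stop("scores must come from screen_pairs()")
  n <- nrow(scores)
  if (n < top_k) stop("need at least top_k scored pairs")
  by_r <- scores$partner[order(-scores$reverse_degree, -scores$f1,
                               scores$partner)]
  by_f <- scores$partner[order(-scores$f1, -scores$reverse_degree,
                               scores$partner)]
  n20 <- ceiling(top_frac * n)
  pool <- union(union(by_r[seq_len(top_k)], by_f[seq_len(top_k)]),
                intersect(by_r[seq_len(n20)], by_f[seq_len(n20)]))
  out <- scores[scores$partner %in% pool, , drop = FALSE]
  out <- out[order(-out$f1, -out$reverse_degree, out$partner), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
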