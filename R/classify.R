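# Applying a signature to samples and scoring the result. Per-pair votes
# compare the two raw expression values within each sample — no
# normalization of any kind — so predictions survive any per-sample
# monotone transform unchanged.

#' Classify samples with a gene-pair signature
#'
#' Each pair votes TFP when the within-sample ordering of anchor and
#' partner matches its direction (exact ties vote TFN); a sample is
#' called TFP when at least half of the pairs vote TFP.
#'
#' @param x numeric matrix, genes x samples.
#' @param sig a `"t2e_signature"`.
#' @return data.frame, one row per sample: `sample_id`, `votes_tfp`,
#'   `n_pairs`, `score` (vote fraction, the classifier's only graded
#'   quantity), `predicted`. The per-pair vote matrix (pairs x samples,
#'   `TRUE` = TFP) is attached as attribute `"pair_votes"`.
#' @export
classify_samples <- function(x, sig) {
  stopifnot(inherits(sig, "t2e_signature"))
  check_expression(x)
  missing <- setdiff(c(sig$anchor, sig$pairs$partner), rownames(x))
  if (length(missing))
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  k <- nrow(sig$pairs)
  votes <- vapply(seq_len(k), function(i) {
    pair_votes(x, sig$anchor, sig$pairs$partner[i], sig$pairs$direction[i])
  }, logical(ncol(x)))
  votes <- t(matrix(votes, nrow = ncol(x), ncol = k))
  dimnames(votes) <- list(sig$pairs$partner, colnames(x))
  n_tfp <- colSums(votes)
  out <- data.frame(sample_id = colnames(x),
                    votes_tfp = as.integer(n_tfp),
                    n_pairs = k,
                    score = n_tfp / k,
                    predicted = ifelse(n_tfp >= k / 2, "TFP", "TFN"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pair_votes") <- votes
  out
}

#' ROC staircase of a discrete score
#'
#' Sweeps the distinct score values as thresholds (predict TFP when
#' `score >= t`), from the strictest down, producing a monotone
#' staircase from (0,0) to (1,1). TFP is the positive class.
#'
#' @param scores numeric vector of per-sample scores, or a predictions
#'   data.frame from [classify_samples()] (its `score` column is used,
#'   matched by `sample_id`).
#' @param labels named TFP/TFN vector.
#' @return data.frame of `fpr`, `tpr` points.
#' @export
roc_points <- function(scores, labels) {
  s <- extract_scores(scores, labels)
  check_labels(labels)
  lab <- unname(labels)
  if (length(unique(lab)) < 2L)
    stop("ROC requires both TFP and TFN samples")
  pos <- s[lab == "TFP"]; neg <- s[lab == "TFN"]
  thresholds <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(pos >= t), numeric(1L))
  fpr <- vapply(thresholds, function(t) mean(neg >= t), numeric(1L))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under the ROC staircase
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`; equals the all-pairs concordance
#'   `P(score_TFP > score_TFN) + 0.5 P(tie)`.
#' @export
auc_score <- function(scores, labels) {
  r <- roc_points(scores, labels)
  n <- nrow(r)
  sum(diff(r$fpr) * (r$tpr[-1L] + r$tpr[-n]) / 2)
}

#' Evaluate predictions against known labels
#'
#' Confusion counts with TFP as the positive class, sensitivity,
#' specificity, accuracy, the harmonic-mean F-1, and the AUC of the
#' vote-fraction score. An optional percentile bootstrap (resampling
#' samples) gives an AUC confidence interval.
#'
#' @param predictions data.frame from [classify_samples()] (columns
#'   `sample_id`, `predicted`, `score`).
#' @param labels named TFP/TFN vector; every predicted sample must be
#'   labelled.
#' @param auc_ci logical; bootstrap an AUC confidence interval?
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @return list: `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1`, `auc`, `roc` (points data.frame), and `auc_ci`
#'   when requested.
#' @export
evaluate_predictions <- function(predictions, labels, auc_ci = FALSE,
                                 n_boot = 2000L, conf = 0.95) {
  check_labels(labels)
  unlab <- setdiff(predictions$sample_id, names(labels))
  if (length(unlab))
    stop("unlabelled sample(s): ", paste(unlab, collapse = ", "))
  truth <- labels[predictions$sample_id]
  pred <- predictions$predicted
  tp <- sum(pred == "TFP" & truth == "TFP")
  fn <- sum(pred == "TFN" & truth == "TFP")
  tn <- sum(pred == "TFN" & truth == "TFN")
  fp <- sum(pred == "TFP" & truth == "TFN")
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  out <- list(tp = tp, fn = fn, tn = tn, fp = fp,
              sensitivity = sen, specificity = spe,
              accuracy = (tp + tn) / length(truth),
              f1 = harmonic_f1(sen, spe),
              auc = auc_score(predictions, truth),
              roc = roc_points(predictions, truth))
  if (auc_ci) {
    s <- predictions$score
    n <- length(s)
    boot <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(truth[idx])) < 2L) NA_real_
      else auc_score(s[idx], stats::setNames(truth[idx], seq_len(n)))
    })
    alpha <- (1 - conf) / 2
    out$auc_ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha),
                                         na.rm = TRUE))
  }
  out
}

extract_scores <- function(scores, labels) {
  if (is.data.frame(scores)) {
    s <- stats::setNames(scores$score, scores$sample_id)[names(labels)]
    if (anyNA(s)) stop("labelled sample(s) missing from predictions")
    return(unname(s))
  }
  if (!is.null(names(scores))) return(unname(scores[names(labels)]))
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  scores
}
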