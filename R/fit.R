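#' Fit a rank-based gene-pair fusion signature
#'
#' The full discovery pipeline on a labelled training matrix:
#' \enumerate{
#'   \item score every gene with five variability metrics and fuse them by
#'     mean-of-ranks ([gene_stability()], [fuse_and_select()]); the top and
#'     bottom quartiles become the reference genes;
#'   \item score every anchored pair by reverse degree and the harmonic
#'     F-1 on within-sample orderings ([screen_pairs()]) and assemble the
#'     candidate pool by the top-20\%/top-10 rules ([candidate_pool()]);
#'   \item greedy forward selection from the ten best seeds under the
#'     majority-vote rule ([forward_select()]).
#' }
#' The fitted signature classifies any expression matrix on any platform:
#' only within-sample orderings of the raw values are used.
#'
#' @param x numeric training matrix, genes x samples (raw scale; any
#'   within-sample monotone transform of it gives the same fit).
#' @param labels named TFP/TFN vector covering columns of `x`; both
#'   classes required.
#' @param anchor anchor gene id (default `"ERG"`).
#' @param quartile stability quartile defining reference genes.
#' @param top_frac,top_k candidate-pool rules (see [candidate_pool()]).
#' @param n_seeds,max_pairs forward-selection controls.
#' @param entropy_bins,outlier_coef stability-metric knobs.
#' @return object of class `"t2e_fit"`: `signature` (a
#'   `"t2e_signature"`), `stability` (fused per-gene table),
#'   `pair_scores`, `candidates`, `training` (an [evaluate_predictions()]
#'   list), `anchor`, `call`.
#' @seealso [predict.t2e_fit()], [classify_samples()],
#'   [evaluate_predictions()]
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 120, n_tfn = 40,
#'                                       n_tfp = 20, seed = 42))
#' fit <- t2e_fit(sim$expression, sim$labels)
#' fit
#' head(predict(fit, sim$expression))
#' @export
t2e_fit <- function(x, labels, anchor = "ERG", quartile = 0.25,
                    top_frac = 0.20, top_k = 10L, n_seeds = 10L,
                    max_pairs = 20L, entropy_bins = 10L,
                    outlier_coef = 1) {
  cl <- match.call()
  check_expression(x)
  check_labels(labels, x, require_both = TRUE)
  if (!anchor %in% rownames(x))
    stop("anchor gene '", anchor, "' not in matrix")
  stab <- gene_stability(x, labels, bins = entropy_bins,
                         outlier_coef = outlier_coef)
  fused <- fuse_and_select(stab, quartile = quartile, anchor = anchor)
  refs <- reference_genes(fused)
  scores <- screen_pairs(x, labels, refs, anchor = anchor)
  pool <- candidate_pool(scores, top_frac = top_frac,
                         top_k = min(top_k, nrow(scores)))
  sig <- forward_select(pool, x, labels, anchor = anchor,
                        n_seeds = n_seeds, max_pairs = max_pairs)
  training <- evaluate_predictions(
    classify_samples(x[, names(labels), drop = FALSE], sig), labels)
  structure(list(signature = sig, stability = fused, pair_scores = scores,
                 candidates = pool, training = training, anchor = anchor,
                 call = cl),
            class = "t2e_fit")
}

#' @export
print.t2e_fit <- function(x, ...) {
  cat("Rank-based gene-pair fusion-status fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Reference genes: %d (%d stable, %d unstable); candidates: %d\n",
              sum(x$stability$category != "neither"),
              sum(x$stability$category == "stable"),
              sum(x$stability$category == "unstable"),
              nrow(x$candidates)))
  print(x$signature)
  cat(sprintf("Training: accuracy %.4f, AUC %.4f\n",
              x$training$accuracy, x$training$auc))
  invisible(x)
}

#' @export
summary.t2e_fit <- function(object, ...) {
  structure(list(signature = object$signature,
                 training = object$training,
                 n_candidates = nrow(object$candidates),
                 n_reference = sum(object$stability$category != "neither")),
            class = "summary.t2e_fit")
}

#' @export
print.summary.t2e_fit <- function(x, ...) {
  print(x$signature)
  with(x$training, {
    cat(sprintf("Confusion (TFP positive): tp %d  fn %d  tn %d  fp %d\n",
                tp, fn, tn, fp))
    cat(sprintf("Sen %.4f  Spe %.4f  Acc %.4f  F-1 %.4f  AUC %.4f\n",
                sensitivity, specificity, accuracy, f1, auc))
  })
  cat(sprintf("Candidates considered: %d; reference genes: %d\n",
              x$n_candidates, x$n_reference))
  invisible(x)
}

#' Screening statistics of the selected pairs
#'
#' @param object a `"t2e_fit"`.
#' @param ... unused.
#' @return data.frame: one row per selected pair with its direction,
#'   reverse degree, sensitivity, specificity and F-1 from screening.
#' @export
coef.t2e_fit <- function(object, ...) {
  sel <- object$pair_scores$partner %in% object$signature$pairs$partner
  out <- object$pair_scores[sel, , drop = FALSE]
  out[match(object$signature$pairs$partner, out$partner), , drop = FALSE]
}

#' Classify new samples with a fitted signature
#'
#' @param object a `"t2e_fit"`.
#' @param newdata numeric matrix, genes x samples, containing the anchor
#'   and all partner genes (raw values; no normalization needed).
#' @param type `"response"` returns the per-sample vote table,
#'   `"score"` just the named vote-fraction vector.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.t2e_fit <- function(object, newdata,
                            type = c("response", "score"), ...) {
  type <- match.arg(type)
  res <- classify_samples(newdata, object$signature)
  if (type == "score") stats::setNames(res$score, res$sample_id) else res
}

#' Plot the training ROC staircase of a fitted signature
#'
#' @param x a `"t2e_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.t2e_fit <- function(x, ...) {
  r <- x$training$roc
  graphics::plot(r$fpr, r$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Training ROC (AUC = %.3f)", x$training$auc),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
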