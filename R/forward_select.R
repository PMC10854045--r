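# Seeded greedy forward selection of a majority-vote pair set. Each of
# the n_seeds highest-F-1 candidates starts its own greedy trace; pairs
# are added while the ensemble F-1 strictly improves; the best trace wins
# (highest F-1, then fewer pairs, then earlier seed). Pure forward
# selection: no removals or swaps.

#' Ensemble F-1 of a set of directed pair votes
#'
#' @param votes logical matrix, pairs x samples: `TRUE` = the pair votes
#'   TFP in that sample.
#' @param is_tfp logical vector over samples (truth).
#' @return list: sensitivity, specificity, f1 of the majority vote
#'   (TFP iff votes_TFP >= half of the pair count).
#' @keywords internal
ensemble_f1 <- function(votes, is_tfp) {
  k <- nrow(votes)
  pred_tfp <- colSums(votes) >= k / 2
  sen <- mean(pred_tfp[is_tfp])
  spe <- mean(!pred_tfp[!is_tfp])
  list(sensitivity = sen, specificity = spe, f1 = harmonic_f1(sen, spe))
}

#' Greedy forward selection of a majority-vote signature
#'
#' @param candidates data.frame from [candidate_pool()] (or
#'   [screen_pairs()]): columns partner, direction, f1 at least.
#' @param x training expression matrix, genes x samples.
#' @param labels named TFP/TFN vector.
#' @param anchor anchor gene id.
#' @param n_seeds number of top-F-1 candidates used as greedy seeds.
#' @param max_pairs safety cap on signature size.
#' @return a `"t2e_signature"` carrying training statistics and the
#'   winning selection trace (data.frame: step, partner, f1).
#' @export
forward_select <- function(candidates, x, labels, anchor = "ERG",
                           n_seeds = 10L, max_pairs = 20L) {
  if (is.null(nrow(candidates)) || nrow(candidates) == 0L)
    stop("candidate pool is empty")
  check_expression(x)
  check_labels(labels, x, require_both = TRUE)
  # canonical order defines seed order and add-step tie-breaking
  ord <- order(-candidates$f1,
               if (!is.null(candidates$reverse_degree))
                 -candidates$reverse_degree else rep(0, nrow(candidates)),
               candidates$partner)
  candidates <- candidates[ord, , drop = FALSE]
  nc <- nrow(candidates)
  is_tfp <- unname(labels == "TFP")
  votes <- t(vapply(seq_len(nc), function(i) {
    pair_votes(x[, names(labels), drop = FALSE], anchor,
               candidates$partner[i], candidates$direction[i])
  }, logical(length(labels))))

  run_seed <- function(seed_i) {
    sel <- seed_i
    best <- ensemble_f1(votes[sel, , drop = FALSE], is_tfp)
    trace <- data.frame(step = 1L, partner = candidates$partner[seed_i],
                        f1 = best$f1, stringsAsFactors = FALSE)
    repeat {
      if (length(sel) >= max_pairs) break
      remaining <- setdiff(seq_len(nc), sel)
      if (!length(remaining)) break
      best_add <- 0L; best_new <- best
      for (i in remaining) {
        cand <- ensemble_f1(votes[c(sel, i), , drop = FALSE], is_tfp)
        if (cand$f1 > best_new$f1) { best_new <- cand; best_add <- i }
      }
      if (best_add == 0L) break
      sel <- c(sel, best_add)
      best <- best_new
      trace <- rbind(trace, data.frame(
        step = length(sel), partner = candidates$partner[best_add],
        f1 = best$f1, stringsAsFactors = FALSE))
    }
    list(sel = sel, stats = best, trace = trace)
  }

  seeds <- seq_len(min(n_seeds, nc))
  runs <- lapply(seeds, run_seed)
  f1s <- vapply(runs, function(r) r$stats$f1, numeric(1L))
  sizes <- vapply(runs, function(r) length(r$sel), integer(1L))
  winner <- runs[[order(-f1s, sizes, seeds)[1L]]]

  t2e_signature(partners = candidates$partner[winner$sel],
                directions = candidates$direction[winner$sel],
                anchor = anchor,
                training = winner$stats,
                trace = winner$trace,
                provenance = "forward-selection")
}

# TFP-vote vector of one directed pair over the columns of x
pair_votes <- function(x, anchor, partner, direction) {
  if (direction == "gt") x[anchor, ] > x[partner, ]
  else x[anchor, ] < x[partner, ]
}
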