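# Shared fixtures, built in code.

# small deterministic expression matrix
tiny_matrix <- function(n_genes = 6L, n_samples = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(round(stats::runif(n_genes * n_samples, 1, 100), 3),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

two_group_labels <- function(n_tfn, n_tfp) {
  stats::setNames(rep(c("TFN", "TFP"), c(n_tfn, n_tfp)),
                  c(paste0("n", seq_len(n_tfn)), paste0("p", seq_len(n_tfp))))
}

# predictions data.frame + labels realizing given confusion counts
preds_from_counts <- function(tp, fn, tn, fp) {
  ids <- paste0("s", seq_len(tp + fn + tn + fp))
  predicted <- rep(c("TFP", "TFN", "TFN", "TFP"), c(tp, fn, tn, fp))
  truth <- rep(c("TFP", "TFP", "TFN", "TFN"), c(tp, fn, tn, fp))
  preds <- data.frame(sample_id = ids, votes_tfp = ifelse(predicted == "TFP", 1L, 0L),
                      n_pairs = 1L, score = ifelse(predicted == "TFP", 1, 0),
                      predicted = predicted, stringsAsFactors = FALSE)
  list(predictions = preds, labels = stats::setNames(truth, ids))
}

# an expression matrix realizing an arbitrary TFP-vote matrix for "gt"
# pairs: anchor fixed at 100, partner below (vote TFP) or above
matrix_from_votes <- function(votes) { # votes: partners x samples, logical
  k <- nrow(votes); n <- ncol(votes)
  x <- rbind(ERG = rep(100, n),
             matrix(ifelse(votes, 50, 150), k, n))
  rownames(x) <- c("ERG", paste0("prt", seq_len(k)))
  colnames(x) <- paste0("s", seq_len(n))
  x
}

# independent harmonic F-1 of a majority vote, re-derived for oracles
oracle_majority_f1 <- function(votes, is_tfp) {
  pred <- colSums(votes) >= nrow(votes) / 2
  sen <- sum(pred & is_tfp) / sum(is_tfp)
  spe <- sum(!pred & !is_tfp) / sum(!is_tfp)
  if (sen + spe == 0) 0 else 2 * sen * spe / (sen + spe)
}
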