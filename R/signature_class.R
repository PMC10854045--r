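# The signature object: an anchor gene plus an ordered set of directed
# partner pairs, classified by majority vote. Direction "gt" means
# E_anchor > E_partner votes TFP; "lt" votes TFP on the reverse ordering.
# Exact ties E_anchor == E_partner always vote TFN (conservative toward
# the negative class: no evidence of anchor elevation).

#' Construct a gene-pair signature
#'
#' @param partners character vector of partner gene ids (unique).
#' @param directions `"gt"` or `"lt"` per pair, recycled if length 1;
#'   `"gt"` means anchor > partner votes TFP.
#' @param anchor anchor gene id (default `"ERG"`).
#' @param training optional list of training statistics
#'   (`f1`, `sensitivity`, `specificity`).
#' @param trace optional data.frame recording the forward-selection path.
#' @param provenance free-text origin note.
#' @return an object of class `"t2e_signature"`.
#' @export
t2e_signature <- function(partners, directions = "gt", anchor = "ERG",
                          training = NULL, trace = NULL,
                          provenance = "user") {
  partners <- as.character(partners)
  if (length(partners) < 1L) stop("a signature needs at least one pair")
  if (anyDuplicated(partners))
    stop("duplicate partner genes in signature")
  directions <- rep_len(as.character(directions), length(partners))
  if (!all(directions %in% c("gt", "lt")))
    stop("directions must be 'gt' or 'lt'")
  if (anchor %in% partners)
    stop("anchor gene cannot be its own partner")
  structure(
    list(anchor = anchor,
         pairs = data.frame(partner = partners, direction = directions,
                            stringsAsFactors = FALSE),
         rule = "TFP iff votes_TFP >= half of pair count",
         training = training, trace = trace, provenance = provenance),
    class = "t2e_signature")
}

#' @export
print.t2e_signature <- function(x, ...) {
  k <- nrow(x$pairs)
  cat("Gene-pair REO signature (", k, " pair", if (k != 1L) "s",
      ", anchor ", x$anchor, ")\n", sep = "")
  rel <- ifelse(x$pairs$direction == "gt", ">", "<")
  cat(paste0("  ", x$anchor, " ", rel, " ", x$pairs$partner,
             "  -> votes TFP"), sep = "\n")
  cat("Rule:", x$rule, "\n")
  if (!is.null(x$training))
    cat(sprintf("Training F-1 %.4f (Sen %.4f, Spe %.4f)\n",
                x$training$f1, x$training$sensitivity,
                x$training$specificity))
  invisible(x)
}

#' @export
predict.t2e_signature <- function(object, newdata, ...) {
  classify_samples(newdata, object)
}

#' The shipped five-pair ERG signature
#'
#' The published five-partner configuration (TNPO1, EXTL2, DPP4, ANG,
#' CHRNA2, each voting TFP when ERG exceeds the partner). Reconstructed
#' from the published figures and discussion — the original directions were
#' never printed — so treat it as a starting point, not a certified model;
#' override with [read_signature()] where a trained file is available.
#'
#' @return a `"t2e_signature"` with 5 pairs and anchor `"ERG"`.
#' @export
default_signature <- function() {
  t2e_signature(partners = c("TNPO1", "EXTL2", "DPP4", "ANG", "CHRNA2"),
                directions = "gt", anchor = "ERG",
                provenance = "reconstructed-from-publication")
}

#' Read / write a signature as JSON
#'
#' The on-disk format is a small JSON object:
#' `{"anchor": ..., "pairs": [{"partner": ..., "direction": ...}, ...],
#'   "rule": ..., "training": {...}}`.
#'
#' @param path path to a JSON file.
#' @return for `read_signature`, a `"t2e_signature"`.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$anchor) || is.null(obj$pairs))
    stop("signature JSON must contain 'anchor' and 'pairs'")
  t2e_signature(partners = obj$pairs$partner,
                directions = obj$pairs$direction,
                anchor = obj$anchor,
                training = obj$training,
                provenance = if (is.null(obj$provenance)) "file"
                             else obj$provenance)
}

#' @rdname read_signature
#' @param sig a `"t2e_signature"`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "t2e_signature"))
  obj <- list(anchor = sig$anchor, pairs = sig$pairs, rule = sig$rule,
              training = sig$training, provenance = sig$provenance)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1L))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
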