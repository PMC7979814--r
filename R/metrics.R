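# Rank-based classification metrics used by the evaluators.
# AUROC uses the Mann-Whitney formulation with ties mid-ranked; average
# precision averages precision over the positive hits of the ranked list.

#' Area under the ROC curve of a score vector
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) ground truth.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("AUROC needs at least one positive and one negative")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision of a score vector
#'
#' Ties are broken deterministically by `tie_ids` (lexicographic) so the
#' value does not depend on input order.
#' @param scores numeric scores, larger = more positive.
#' @param labels logical ground truth.
#' @param tie_ids optional character ids used to break score ties.
#' @return average precision in [0, 1].
#' @export
average_precision <- function(scores, labels, tie_ids = NULL) {
  labels <- as.logical(labels)
  if (!sum(labels)) stop("average precision needs at least one positive")
  if (is.null(tie_ids)) tie_ids <- as.character(seq_along(scores))
  o <- order(-scores, tie_ids)
  lab <- labels[o]
  hits <- cumsum(lab)
  prec_at_pos <- hits[lab] / which(lab)
  mean(prec_at_pos)
}

#' Recall among the top-k ranked candidates
#' @param scores,labels as in [auroc()].
#' @param k cutoff (default 50); when fewer than `k` candidates exist,
#'   all are taken and recall is 1 whenever any positive exists.
#' @param tie_ids optional character ids used to break score ties.
#' @return recall in [0, 1].
#' @export
recall_at_k <- function(scores, labels, k = 50L, tie_ids = NULL) {
  labels <- as.logical(labels)
  if (!sum(labels)) stop("recall@k needs at least one positive")
  if (is.null(tie_ids)) tie_ids <- as.character(seq_along(scores))
  o <- order(-scores, tie_ids)
  top <- o[seq_len(min(k, length(o)))]
  sum(labels[top]) / sum(labels)
}
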