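# Threshold-free evaluation against a gold standard.

#' Expand a gold standard into a per-row label vector
#'
#' Positives become 1, explicit negatives 0. Candidate pairs absent from the
#' gold standard are \code{NA} (excluded from evaluation) unless
#' \code{assume_absent_negative} is set, in which case they count as
#' negatives.
#'
#' @param gold an \code{\link{edge_label_set}}.
#' @param n universe size.
#' @param assume_absent_negative treat unlisted candidates as negatives.
#' @return Integer vector of 0/1/NA labels of length n.
#' @export
gold_labels <- function(gold, n, assume_absent_negative = FALSE) {
  lab <- rep(if (assume_absent_negative) 0L else NA_integer_, n)
  lab[gold$negatives] <- 0L
  lab[gold$positives] <- 1L
  lab
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a uniformly random positive
#' outscores a uniformly random negative, with ties counted one half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (NA entries are dropped).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("AUROC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation over descending score thresholds:
#' tied scores are processed as one block, and each block contributes its
#' recall increment times the precision attained after including it.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("AUPRC needs at least one positive and one negative")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  block <- cumsum(!duplicated(s)) # tied scores share a block
  tp_b <- tapply(y, block, sum)
  n_b <- tabulate(block)
  tp <- cumsum(tp_b)
  pred <- cumsum(n_b)
  prec <- tp / pred
  rec <- tp / np
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Per-iteration evaluation of a fitted run
#'
#' Mirrors a per-iteration results table: one row per learning round with
#' the AUROC and AUPRC of that round's mean-over-views scores.
#'
#' @param fit a \code{genere_fit} from \code{\link{run_genere}}.
#' @param gold an \code{\link{edge_label_set}}; required.
#' @param assume_absent_negative see \code{\link{gold_labels}}.
#' @return data.frame with columns \code{iteration}, \code{auroc},
#'   \code{auprc}, \code{n_pos}, \code{n_neg}.
#' @export
evaluate_run <- function(fit, gold, assume_absent_negative = FALSE) {
  if (missing(gold) || is.null(gold))
    stop("a gold standard is required: supply gold (e.g. via --gold)")
  n <- length(fit$scores)
  lab <- gold_labels(gold, n, assume_absent_negative)
  do.call(rbind, lapply(fit$iterations, function(it) {
    data.frame(iteration = it$iteration,
               auroc = auroc(it$scores, lab),
               auprc = auprc(it$scores, lab),
               n_pos = sum(lab == 1, na.rm = TRUE),
               n_neg = sum(lab == 0, na.rm = TRUE))
  }))
}
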