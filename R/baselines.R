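# Unsupervised rank-combination baselines.

#' Per-method rank matrix
#'
#' Ranks every interaction within each base method, rank 1 = highest score,
#' ties sharing the average rank (so each column's mean is (N+1)/2).
#'
#' @param table an \code{\link{interaction_table}}.
#' @return Numeric matrix of ranks, one row per interaction.
#' @export
rank_matrix <- function(table) {
  apply(table$scores, 2, function(x) rank(-x, ties.method = "average"))
}

# Rescale a lower-is-better rank statistic to a higher-is-better score in
# [0, 1], keeping the package's score orientation uniform.
rank_to_score <- function(r, N) {
  if (N == 1L) return(rep(1, length(r)))
  (N - r) / (N - 1)
}

#' Borda rank aggregation
#'
#' Averages each interaction's per-method ranks and rescales so that higher
#' is better (Borda consensus of the base methods).
#'
#' @param table an \code{\link{interaction_table}}.
#' @return Numeric score vector (higher = more confident).
#' @export
borda_combine <- function(table) {
  R <- rank_matrix(table)
  rank_to_score(rowMeans(R), nrow(R))
}

#' Top-k rank combination
#'
#' For each interaction takes the k-th best (k-th smallest) of its per-method
#' ranks: k = 1 is the optimistic consensus, k = s the most conservative.
#' Rescaled so that higher is better.
#'
#' @param table an \code{\link{interaction_table}}.
#' @param k order statistic, \code{1 <= k <=} number of methods.
#' @return Numeric score vector (higher = more confident).
#' @export
topk_combine <- function(table, k) {
  s <- ncol(table$scores)
  if (k < 1 || k > s) stop("k must be in [1, number of methods]")
  R <- rank_matrix(table)
  kth <- apply(R, 1, function(r) sort(r, partial = k)[k])
  rank_to_score(kth, nrow(R))
}

#' Sweep the top-k combiner over k
#'
#' @param table an \code{\link{interaction_table}}.
#' @param k_max largest k considered; capped at the number of methods
#'   (default 20, the range beyond which the order statistic is known to
#'   deteriorate).
#' @return Named list of score vectors, one per k in 1..min(k_max, s).
#' @export
topk_sweep <- function(table, k_max = 20L) {
  ks <- seq_len(min(k_max, ncol(table$scores)))
  stats::setNames(lapply(ks, function(k) topk_combine(table, k)),
                  paste0("k", ks))
}
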