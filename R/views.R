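# Column standardization used before both clustering routes; a zero-variance
# column is left at zero rather than producing NaN.
standardize_columns <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
}

new_view_partition <- function(assignment, V_requested, method, seed = NA_integer_) {
  # canonical renumbering: views numbered 1..V_eff in order of first appearance,
  # empty clusters collapsed
  levels_seen <- unique(assignment)
  assignment <- match(assignment, levels_seen)
  V_eff <- length(levels_seen)
  structure(list(assignment = assignment, V = V_eff,
                 V_requested = as.integer(V_requested),
                 method = method, seed = seed,
                 degenerate = V_eff < V_requested),
            class = "view_partition")
}

#' @export
print.view_partition <- function(x, ...) {
  cat(sprintf("view_partition (%s): %d view(s) over %d features%s\n",
              x$method, x$V, length(x$assignment),
              if (x$degenerate) sprintf(" [collapsed from %d requested]",
                                        x$V_requested) else ""))
  invisible(x)
}

#' Partition features into views by PCA loadings
#'
#' Computes the top-V principal components of the standardized feature columns
#' and assigns each base method to the component on which it loads most
#' strongly in absolute value (a strong negative loading marks an equally
#' strong association). Ties go to the lowest component index. Components
#' attracting no feature are collapsed, reducing the effective number of views
#' (flagged \code{degenerate}).
#'
#' @param table an \code{\link{interaction_table}}.
#' @param V requested number of views, \code{1 <= V <=} number of methods.
#' @return A \code{view_partition}: integer \code{assignment} (one view index
#'   per method, 1-based), effective \code{V}, \code{method}, and a
#'   \code{degenerate} flag.
#' @export
cluster_features_pca <- function(table, V) {
  s <- ncol(table$scores)
  if (V < 1) stop("V must be >= 1")
  if (V > s) stop("V exceeds the number of features")
  if (nrow(table$scores) < 2) stop("need at least 2 interactions")
  if (V == 1L)
    return(new_view_partition(rep(1L, s), V, "pca"))
  X <- standardize_columns(table$scores)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  ncomp <- min(V, ncol(pc$rotation))
  load <- abs(pc$rotation[, seq_len(ncomp), drop = FALSE])
  assignment <- apply(load, 1, which.max) # which.max takes lowest index on ties
  new_view_partition(as.integer(assignment), V, "pca")
}

#' Partition features into views by K-means on feature vectors
#'
#' Each base method is represented as its (standardized) column over the
#' candidate interactions, optionally row-subsampled for scalability, and the
#' methods are clustered with Euclidean K-means. The best of \code{restarts}
#' random initializations (by within-cluster sum of squares) is kept.
#' Duplicate feature columns are collapsed before clustering so they are
#' always co-assigned; if fewer distinct columns than V exist the effective
#' number of views is reduced.
#'
#' @inheritParams cluster_features_pca
#' @param seed RNG seed controlling initialization and row subsampling.
#' @param restarts number of random initializations (default 10).
#' @param row_subsample maximum number of interaction rows used as the
#'   clustering dimensions (default 50000); subsampling preserves column
#'   geometry on large universes.
#' @return A \code{view_partition}.
#' @export
cluster_features_kmeans <- function(table, V, seed = 1L, restarts = 10L,
                                    row_subsample = 50000L) {
  s <- ncol(table$scores)
  if (V < 1) stop("V must be >= 1")
  if (V > s) stop("V exceeds the number of features")
  if (nrow(table$scores) < 2) stop("need at least 2 interactions")
  if (V == 1L)
    return(new_view_partition(rep(1L, s), V, "kmeans", seed))
  X <- table$scores
  if (nrow(X) > row_subsample) {
    set.seed(seed)
    X <- X[sample.int(nrow(X), row_subsample), , drop = FALSE]
  }
  P <- t(standardize_columns(X)) # one row per feature
  keys <- apply(P, 1, paste, collapse = "\r")
  uniq <- !duplicated(keys)
  Pu <- P[uniq, , drop = FALSE]
  if (nrow(Pu) <= V) {
    # each distinct column alone in a view; duplicates co-assigned
    ucl <- seq_len(nrow(Pu))
  } else {
    set.seed(seed)
    km <- stats::kmeans(Pu, centers = V, nstart = restarts, iter.max = 100L)
    ucl <- km$cluster
  }
  # map every feature to its distinct representative's cluster
  rep_idx <- match(keys, keys[uniq])
  new_view_partition(as.integer(ucl[rep_idx]), V, "kmeans", seed)
}

#' Split an interaction table into per-view tables
#'
#' @param table an \code{\link{interaction_table}}.
#' @param partition a \code{view_partition} over its columns.
#' @return A list of V \code{interaction_table}s, the v-th holding exactly the
#'   columns assigned to view v in the original row order.
#' @export
project_views <- function(table, partition) {
  stopifnot(length(partition$assignment) == ncol(table$scores))
  lapply(seq_len(partition$V), function(v) {
    cols <- which(partition$assignment == v)
    interaction_table(table$regulator, table$target,
                      table$scores[, cols, drop = FALSE],
                      table$methods[cols], table$normalization)
  })
}
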