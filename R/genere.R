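# Iteration engine: initialize the labeled set, loop views x iterations,
# exchange cross-view scores, update per-view labeled sets with retraction,
# and emit the final averaged posterior.

#' Build a run configuration
#'
#' @param V number of views (>= 1).
#' @param clustering \code{"kmeans"} or \code{"pca"} feature clustering.
#' @param delta fraction of the candidate universe promoted to the labeled
#'   set at each update (and used to size a cold-start seed); default 0.005.
#' @param max_iter number of learning rounds; round i trains on the label
#'   sets produced by i - 1 updates, so round 1 trains on the initial seed.
#' @param gamma unlabeled coverage target for bagging (default 0.99).
#' @param n_mode \code{"balance"} (n = |labeled|) or \code{"double"}.
#' @param max_W bagging sample-count guard (default 500).
#' @param classifier \code{"linear_svm_platt"} or \code{"logistic"}.
#' @param seed master seed; per-view, per-iteration seeds are derived from it
#'   deterministically.
#' @param cold_start force cold-start label initialization even when a gold
#'   standard is supplied (the gold standard is then used only for
#'   diagnostics).
#' @param restarts,row_subsample K-means clustering controls.
#' @return A \code{genere_config} list.
#' @export
genere_config <- function(V = 3L, clustering = c("kmeans", "pca"),
                          delta = 0.005, max_iter = 5L, gamma = 0.99,
                          n_mode = c("balance", "double"), max_W = 500L,
                          classifier = c("linear_svm_platt", "logistic"),
                          seed = 42L, cold_start = FALSE,
                          restarts = 10L, row_subsample = 50000L) {
  clustering <- match.arg(clustering)
  n_mode <- match.arg(n_mode)
  classifier <- match.arg(classifier)
  stopifnot(V >= 1, delta > 0, delta < 1, max_iter >= 1,
            gamma > 0, gamma < 1)
  structure(list(V = as.integer(V), clustering = clustering, delta = delta,
                 max_iter = as.integer(max_iter), gamma = gamma,
                 n_mode = n_mode, max_W = as.integer(max_W),
                 classifier = classifier, seed = as.integer(seed),
                 cold_start = cold_start, restarts = as.integer(restarts),
                 row_subsample = as.integer(row_subsample)),
            class = "genere_config")
}

# Deterministic per-(view, iteration) seed below 2^31, derived from the
# master seed so ensembles get independent but reproducible randomness.
derive_seed <- function(master, v, i) {
  as.integer((((master %% 1000003) + 1) * 2063 + v * 9973 + i * 389) %% 2147483629L)
}

#' Initialize the labeled set
#'
#' With a non-empty gold seed, the initial positives are exactly its edges.
#' Otherwise (cold start, the worst-case scenario with no confirmed
#' interaction) the top \code{ceiling(delta * N)} interactions by unweighted
#' mean base-method score are taken, ties broken by lexicographic
#' (regulator, target) order.
#'
#' @param table an \code{\link{interaction_table}}.
#' @param gold_seed an \code{\link{edge_label_set}} or \code{NULL}.
#' @param delta cold-start seed fraction of the universe.
#' @return Sorted integer vector of initial labeled row indices (L0).
#' @export
initialize_labels <- function(table, gold_seed = NULL, delta = 0.005) {
  N <- nrow(table$scores)
  if (!is.null(gold_seed) && length(gold_seed$positives) > 0L)
    return(sort(gold_seed$positives))
  k <- ceiling(delta * N)
  if (k < 1) stop("delta too small for universe")
  avg <- rowMeans(table$scores)
  # rows are lexicographically sorted, so index order is the tie-break
  sort(order(-avg, seq_len(N), method = "radix")[seq_len(k)])
}

#' Combine the scores of the other views
#'
#' The cross-view reliability of an interaction for view v is the unweighted
#' mean of the per-view posteriors over all views z != v. With a single view
#' there is no other view and the view's own scores are returned.
#'
#' @param per_view_scores list of V numeric score vectors.
#' @param v view index (1-based).
#' @return Numeric combined score vector.
#' @export
combine_other_views <- function(per_view_scores, v) {
  V <- length(per_view_scores)
  if (V == 1L) return(per_view_scores[[1]])
  others <- per_view_scores[-v]
  Reduce(`+`, others) / (V - 1)
}

#' Update a view's labeled set with retraction
#'
#' The next labeled set is the union of the permanent initial seed L0 and the
#' top \code{ceiling(delta * N)} interactions by combined cross-view score.
#' Ties (which arise when the combined posteriors saturate at 1) are broken
#' by \code{tiebreak} when supplied -- the engine passes the combined
#' uncapped ratio, so saturated interactions are ordered by the strength of
#' the evidence rather than arbitrarily -- and lexicographically last.
#' Interactions promoted at an earlier iteration that fall out of the top
#' set are retracted.
#'
#' @param combined combined score vector over the universe.
#' @param delta top fraction promoted.
#' @param L0 permanent initial labeled indices.
#' @param tiebreak optional secondary score vector for ordering ties.
#' @return Sorted integer vector of labeled row indices.
#' @export
update_labeled_set <- function(combined, delta, L0, tiebreak = NULL) {
  N <- length(combined)
  k <- ceiling(delta * N)
  if (is.null(tiebreak)) tiebreak <- numeric(N)
  top <- order(-combined, -tiebreak, seq_len(N), method = "radix")[seq_len(k)]
  sort(union(L0, top))
}

#' Run the full iterative multi-view reconstruction
#'
#' Phase 1 partitions the base methods into views and initializes the labeled
#' set; each subsequent round fits one PU ensemble per view on that view's
#' current labeled set, scores every candidate interaction, and promotes the
#' cross-view top fraction into the next round's labeled sets (retracting
#' earlier promotions that fell out, never the initial seed). The final output
#' is the unweighted mean over views of the last round's posteriors.
#'
#' Rounds are reported 0-based by the number of label updates their training
#' sets have undergone: iteration 0 is the round trained on the initial seed.
#'
#' @param table an \code{\link{interaction_table}}.
#' @param config a \code{\link{genere_config}}.
#' @param gold an \code{\link{edge_label_set}} used for per-iteration
#'   AUROC/AUPRC diagnostics, and for seeding the labeled set unless
#'   \code{config$cold_start} is set.
#' @param assume_absent_negative passed to the evaluation of diagnostics:
#'   treat candidate pairs absent from the gold standard as negatives.
#' @return A \code{genere_fit}: \code{scores} (final posterior per
#'   interaction), \code{partition}, \code{L0}, \code{iterations} (one record
#'   per round: mean scores, per-view label sizes, churn, c, W, optional
#'   AUROC/AUPRC), and \code{config}.
#' @export
run_genere <- function(table, config = genere_config(), gold = NULL,
                       assume_absent_negative = TRUE) {
  N <- nrow(table$scores)
  partition <- switch(config$clustering,
    pca = cluster_features_pca(table, config$V),
    kmeans = cluster_features_kmeans(table, config$V, seed = config$seed,
                                     restarts = config$restarts,
                                     row_subsample = config$row_subsample))
  views <- project_views(table, partition)
  V <- partition$V
  seed_gold <- if (config$cold_start) NULL else gold
  L0 <- initialize_labels(table, seed_gold, config$delta)
  labeled <- rep(list(L0), V)
  iterations <- vector("list", config$max_iter)
  fv <- matrix(NA_real_, N, V) # capped posteriors, emitted
  rv <- matrix(NA_real_, N, V) # uncapped ratios, drive label updates
  for (i in seq_len(config$max_iter)) {
    ens_info <- vector("list", V)
    for (v in seq_len(V)) {
      ens <- fit_view_ensemble(views[[v]], labeled[[v]],
                               n_mode = config$n_mode, gamma = config$gamma,
                               seed = derive_seed(config$seed, v, i),
                               max_W = config$max_W,
                               classifier = config$classifier)
      fv[, v] <- ens$f
      rv[, v] <- ens$ratio
      ens_info[[v]] <- list(W = ens$W, n = ens$n,
                            label_frequency = ens$label_frequency)
    }
    # average the uncapped Elkan-Noto estimates across views, then cap: a
    # per-view cap would flatten the strongest view over its whole top set
    # and leave the top of the combined ranking to the weaker views' noise
    mean_scores <- pmin(rowMeans(rv), 1)
    per_view_f <- lapply(seq_len(V), function(v) fv[, v])
    per_view_ratio <- lapply(seq_len(V), function(v) rv[, v])
    new_labeled <- lapply(seq_len(V), function(v)
      update_labeled_set(combine_other_views(per_view_f, v), config$delta,
                         L0, combine_other_views(per_view_ratio, v)))
    churn <- vapply(seq_len(V), function(v) {
      c(added = length(setdiff(new_labeled[[v]], labeled[[v]])),
        removed = length(setdiff(labeled[[v]], new_labeled[[v]])))
    }, numeric(2))
    rec <- list(iteration = i - 1L, scores = mean_scores,
                per_view_scores = fv,
                label_sizes = lengths(labeled),
                next_label_sizes = lengths(new_labeled),
                churn_added = churn["added", ],
                churn_removed = churn["removed", ],
                label_frequency = vapply(ens_info, `[[`, numeric(1),
                                         "label_frequency"),
                W = vapply(ens_info, `[[`, numeric(1), "W"))
    if (!is.null(gold)) {
      lab <- gold_labels(gold, N, assume_absent_negative)
      rec$auroc <- auroc(mean_scores, lab)
      rec$auprc <- auprc(mean_scores, lab)
    }
    iterations[[i]] <- rec
    labeled <- new_labeled
  }
  structure(list(scores = iterations[[config$max_iter]]$scores,
                 partition = partition, L0 = L0,
                 iterations = iterations, config = config),
            class = "genere_fit")
}

#' @export
print.genere_fit <- function(x, ...) {
  cat(sprintf("genere_fit: %d interactions, %d view(s), %d round(s)\n",
              length(x$scores), x$partition$V, length(x$iterations)))
  if (!is.null(x$iterations[[1]]$auroc)) {
    a <- vapply(x$iterations, `[[`, numeric(1), "auroc")
    cat("per-iteration AUROC:", paste(sprintf("%.4f", a), collapse = " "), "\n")
  }
  invisible(x)
}

#' One-view, one-iteration baseline
#'
#' The degenerate configuration with a single view holding all base methods
#' and a single learning round: one PU ensemble fit on the initial labeled
#' set, no cross-view exchange. Matches \code{\link{run_genere}} with
#' \code{V = 1, max_iter = 1} bit-for-bit under equal seeds.
#'
#' @inheritParams run_genere
#' @param delta,gamma,n_mode,max_W,classifier,seed as in
#'   \code{\link{genere_config}}.
#' @return A numeric posterior score vector over the universe.
#' @export
run_1vi <- function(table, delta = 0.005, gamma = 0.99,
                    n_mode = c("balance", "double"), max_W = 500L,
                    classifier = c("linear_svm_platt", "logistic"),
                    seed = 42L, gold = NULL, cold_start = FALSE) {
  n_mode <- match.arg(n_mode)
  classifier <- match.arg(classifier)
  seed_gold <- if (cold_start) NULL else gold
  L0 <- initialize_labels(table, seed_gold, delta)
  ens <- fit_view_ensemble(table, L0, n_mode = n_mode, gamma = gamma,
                           seed = derive_seed(seed, 1L, 1L), max_W = max_W,
                           classifier = classifier)
  ens$f
}
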