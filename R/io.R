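# Internal pair key: regulator and target joined with a tab (tabs cannot
# occur inside gene identifiers read from TSV files).
pair_key <- function(regulator, target) paste(regulator, target, sep = "\t")

#' Construct an interaction table
#'
#' The central container of the package: every candidate directed interaction
#' (ordered gene pair, self-loops excluded) together with one score column per
#' base inference method. Rows are kept in lexicographic (regulator, target)
#' byte order so that all downstream tie-breaking is deterministic.
#'
#' @param regulator,target character vectors of equal length naming the
#'   directed pairs.
#' @param scores numeric matrix with one row per pair and one column per
#'   base method.
#' @param methods character vector of base-method identifiers (column names).
#' @param normalization one of \code{"none"}, \code{"rank"}, \code{"minmax"};
#'   records how \code{scores} were normalized.
#' @return An object of class \code{interaction_table} with elements
#'   \code{regulator}, \code{target}, \code{scores}, \code{methods},
#'   \code{genes}, \code{normalization}.
#' @export
interaction_table <- function(regulator, target, scores, methods,
                              normalization = "none") {
  stopifnot(length(regulator) == length(target))
  scores <- as.matrix(scores)
  if (nrow(scores) != length(regulator))
    stop("scores must have one row per pair")
  if (ncol(scores) != length(methods))
    stop("scores must have one column per method")
  if (any(regulator == target))
    stop("self-loops are not allowed in an interaction table")
  keys <- pair_key(regulator, target)
  if (anyDuplicated(keys))
    stop("duplicate pairs in interaction table")
  ord <- order(regulator, target, method = "radix")
  scores <- scores[ord, , drop = FALSE]
  colnames(scores) <- methods
  structure(
    list(regulator = regulator[ord], target = target[ord], scores = scores,
         methods = methods,
         genes = sort(unique(c(regulator, target)), method = "radix"),
         normalization = normalization),
    class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table: %d pairs x %d methods (%d genes), normalization = %s\n",
              nrow(x$scores), ncol(x$scores), length(x$genes), x$normalization))
  invisible(x)
}

#' @export
dim.interaction_table <- function(x) dim(x$scores)

#' Construct an edge label set
#'
#' Positive (and optionally negative) directed interactions indexed against
#' the rows of an \code{\link{interaction_table}} universe. Negatives are
#' only populated when read from a gold-standard file that lists them
#' explicitly (flag 0).
#'
#' @param positives integer row indices of positive pairs.
#' @param n_universe number of rows in the universe table.
#' @param negatives integer row indices of explicit negatives.
#' @return An object of class \code{edge_label_set}.
#' @export
edge_label_set <- function(positives, n_universe, negatives = integer(0)) {
  positives <- sort(unique(as.integer(positives)))
  negatives <- sort(unique(as.integer(negatives)))
  if (length(positives) && (min(positives) < 1 || max(positives) > n_universe))
    stop("positive indices outside universe")
  if (length(intersect(positives, negatives)))
    stop("a pair cannot be both positive and negative")
  structure(list(positives = positives, negatives = negatives,
                 n_universe = as.integer(n_universe)),
            class = "edge_label_set")
}

#' @export
print.edge_label_set <- function(x, ...) {
  cat(sprintf("edge_label_set: %d positives, %d explicit negatives over %d candidates\n",
              length(x$positives), length(x$negatives), x$n_universe))
  invisible(x)
}

#' Read a ranked edge-score file
#'
#' Parses one base method's predictions in the DREAM dialect: tab-separated
#' lines \code{regulator TAB target TAB score}, no header, typically sorted by
#' descending confidence (the order is not relied upon). Self-loops are
#' dropped with a warning; when a pair occurs more than once the last
#' occurrence wins (warning).
#'
#' @param path path to a TSV file.
#' @return A data.frame with columns \code{regulator}, \code{target},
#'   \code{score}.
#' @export
read_edge_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty edge-score file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 bad[1], path))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score))
    stop(sprintf("malformed line %d in %s: score '%s' is not numeric",
                 which(is.na(score))[1], path, m[which(is.na(score))[1], 3]))
  df <- data.frame(regulator = m[, 1], target = m[, 2], score = score,
                   stringsAsFactors = FALSE)
  self <- df$regulator == df$target
  if (any(self)) {
    warning(sprintf("%d self-loop(s) dropped from %s", sum(self), path))
    df <- df[!self, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable edges in ", path)
  keys <- pair_key(df$regulator, df$target)
  if (anyDuplicated(keys)) {
    warning(sprintf("%d duplicate pair(s) in %s: last occurrence kept",
                    sum(duplicated(keys)), path))
    df <- df[!duplicated(keys, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# Average-rank normalization of one score column to [0, 1] (higher score ->
# higher value; ties share the mean rank). Single row -> 0.5.
rank_unit <- function(x) {
  n <- length(x)
  if (n == 1L) return(0.5)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

minmax_unit <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the interaction-by-method feature table
#'
#' Takes one parsed score list per base method (see
#' \code{\link{read_edge_scores}}) and builds the joint feature table over the
#' union of all scored pairs. Pairs missing from a method receive the
#' \code{missing_policy} fill for that column before normalization.
#'
#' @param method_scores named list of data.frames with columns
#'   \code{regulator}, \code{target}, \code{score}; names become method ids.
#' @param normalization per-column normalization: \code{"rank"} (average rank
#'   scaled to [0,1]; the default, making incomparable score scales
#'   comparable), \code{"minmax"}, or \code{"none"}.
#' @param missing_policy value given to pairs a method did not score:
#'   \code{"zero"} or \code{"min"} (the column minimum).
#' @param dense if \code{TRUE}, expand the universe to all ordered non-self
#'   pairs of the observed genes rather than the union of scored pairs.
#' @return An \code{\link{interaction_table}}.
#' @export
assemble_feature_table <- function(method_scores,
                                   normalization = c("rank", "minmax", "none"),
                                   missing_policy = c("zero", "min"),
                                   dense = FALSE) {
  normalization <- match.arg(normalization)
  missing_policy <- match.arg(missing_policy)
  if (length(method_scores) == 0L) stop("need at least one base method")
  if (is.null(names(method_scores)) || any(!nzchar(names(method_scores))))
    names(method_scores) <- paste0("method", seq_along(method_scores))
  if (dense) {
    genes <- sort(unique(unlist(lapply(method_scores, function(d)
      c(d$regulator, d$target)))), method = "radix")
    grid <- expand.grid(target = genes, regulator = genes,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$regulator != grid$target, ]
    keys <- pair_key(grid$regulator, grid$target)
    reg <- grid$regulator; tgt <- grid$target
  } else {
    all_keys <- unlist(lapply(method_scores, function(d)
      pair_key(d$regulator, d$target)), use.names = FALSE)
    keys <- unique(all_keys)
    split_keys <- strsplit(keys, "\t", fixed = TRUE)
    reg <- vapply(split_keys, `[`, character(1), 1L)
    tgt <- vapply(split_keys, `[`, character(1), 2L)
  }
  n <- length(keys)
  scores <- matrix(NA_real_, n, length(method_scores))
  for (k in seq_along(method_scores)) {
    d <- method_scores[[k]]
    idx <- match(pair_key(d$regulator, d$target), keys)
    scores[idx[!is.na(idx)], k] <- d$score[!is.na(idx)]
    miss <- is.na(scores[, k])
    if (any(miss)) {
      fill <- if (missing_policy == "zero") 0 else
        if (all(miss)) 0 else min(scores[!miss, k])
      scores[miss, k] <- fill
    }
  }
  if (normalization == "rank") scores <- apply(scores, 2, rank_unit)
  if (normalization == "minmax") scores <- apply(scores, 2, minmax_unit)
  if (n == 1L) scores <- matrix(scores, nrow = 1L)
  interaction_table(reg, tgt, scores, names(method_scores), normalization)
}

#' Read a gold-standard edge list
#'
#' Lines are \code{regulator TAB target TAB flag} with flag 1 marking an
#' experimentally supported interaction and 0 an explicit negative. Pairs
#' outside the candidate universe are excluded and counted in a message.
#'
#' @param path TSV file path.
#' @param universe the \code{\link{interaction_table}} defining candidate
#'   pairs.
#' @return An \code{\link{edge_label_set}}.
#' @export
read_gold_standard <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s", bad[1], path))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  if (!all(m[, 3] %in% c("0", "1")))
    stop("gold-standard flag must be 0 or 1 in ", path)
  keys <- pair_key(m[, 1], m[, 2])
  idx <- match(keys, pair_key(universe$regulator, universe$target))
  outside <- sum(is.na(idx))
  if (outside > 0)
    message(sprintf("%d gold-standard pair(s) outside the candidate universe were excluded",
                    outside))
  flag <- m[, 3] == "1"
  edge_label_set(positives = idx[flag & !is.na(idx)],
                 n_universe = nrow(universe$scores),
                 negatives = idx[!flag & !is.na(idx)])
}

#' Write ranked predictions
#'
#' Writes a score vector over the universe in the DREAM dialect, sorted by
#' descending score with ties broken by (regulator, target) lexicographic
#' order for determinism.
#'
#' @param scores numeric vector, one score per universe row.
#' @param universe the \code{\link{interaction_table}}.
#' @param path output file path.
#' @export
write_ranked_predictions <- function(scores, universe, path) {
  if (length(scores) == 0L) {
    warning("empty score vector: writing empty file")
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(length(scores) == nrow(universe$scores), all(is.finite(scores)))
  ord <- order(-scores, universe$regulator, universe$target, method = "radix")
  writeLines(sprintf("%s\t%s\t%.6f", universe$regulator[ord],
                     universe$target[ord], scores[ord]), path)
  invisible(path)
}
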