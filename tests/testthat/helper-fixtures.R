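# Fixture builders shared across the suite.

# A small interaction table with the given score matrix; genes/pairs are
# synthesized deterministically.
make_table <- function(scores, normalization = "none") {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  genes <- sprintf("g%03d", seq_len(ceiling(sqrt(n)) + 1))
  grid <- expand.grid(target = genes, regulator = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$regulator != grid$target, ][seq_len(n), ]
  interaction_table(grid$regulator, grid$target, scores,
                    paste0("m", seq_len(ncol(scores))), normalization)
}

# Feature blocks for view-recovery tests: V mutually uncorrelated blocks of
# highly intra-correlated columns (shared latent + private noise). Blocks
# get distinct noise levels by default: families differ in how tightly
# their methods agree, which also keeps the leading eigenvalues of the
# correlation matrix non-degenerate (equally redundant equal-size blocks
# have interchangeable principal components).
make_block_table <- function(n_rows = 400, block_sizes = c(5, 5, 5),
                             noise = c(0.05, 0.3, 0.6), seed = 1) {
  set.seed(seed)
  noise <- rep_len(noise, length(block_sizes))
  cols <- do.call(cbind, lapply(seq_along(block_sizes), function(b) {
    latent <- stats::rnorm(n_rows)
    sapply(seq_len(block_sizes[b]), function(i)
      latent + stats::rnorm(n_rows, 0, noise[b]))
  }))
  make_table(cols)
}

block_labels <- function(block_sizes) rep(seq_along(block_sizes), block_sizes)

# Adjusted Rand index between two partitions (small helper used only to
# check view recovery; mclust::adjustedRandIndex is used as the independent
# cross-check in the acceptance suite).
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Write a DREAM-style TSV of edges.
write_edge_file <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(sprintf("%s\t%s\t%s", df[[1]], df[[2]], df[[3]]), path)
  path
}

# Brute-force AUROC oracle: exhaustive pairwise comparison.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}
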