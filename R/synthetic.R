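# Synthetic ground-truth networks and base-method score matrices.
#
# The generator emulates the object the ensemble consumes -- per-method edge
# score vectors organized in correlated groups (methods within a group share
# a latent signal, groups differ in informativeness) -- rather than the
# expression-kinetics pipeline that would produce them from data. This keeps
# the oracle posterior analytic and the package self-contained.

#' Synthetic dataset configuration
#'
#' @param n_genes number of genes (>= 10).
#' @param topology \code{"scale_free"} (directed preferential attachment with
#'   regulator hubs) or \code{"erdos_renyi"}.
#' @param mean_degree target average node degree (in + out); the defaults
#'   mirror small curated regulatory sub-networks (about 100 genes, average
#'   degree about 2.4).
#' @param n_groups number of base-method groups (redundant method families).
#' @param methods_per_group methods per group; total s = n_groups *
#'   methods_per_group.
#' @param informativeness per-group probability in [0, 1] that the group's
#'   latent signal reflects the true edge indicator for a given interaction
#'   (1 = the group detects every edge; lower values leave a random subset of
#'   edges indistinguishable from noise for that group).
#' @param within_group_corr target pairwise correlation in [0, 1] of the
#'   methods within a group; the private-noise variance of each method is
#'   matched to it (1 with \code{noise_sd = 0} gives identical columns).
#' @param detection_corr Gaussian-copula correlation in [0, 1) of the
#'   detection events across groups: edges differ in difficulty, and an edge
#'   that one method family detects is more likely to be detected by the
#'   others too (0 = independent detections; marginal detection probability
#'   stays \code{informativeness} regardless).
#' @param noise_sd standard deviation of each method's private Gaussian
#'   noise.
#' @param scar_label_freq probability that a true edge is retained as labeled
#'   by \code{\link{generate_scar_labels}}.
#' @param seed RNG seed; every output is reproducible from (config, seed).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_genes = 100L, topology = c("scale_free", "erdos_renyi"),
                         mean_degree = 2.42, n_groups = 3L,
                         methods_per_group = 5L,
                         informativeness = c(0.9, 0.6, 0.3),
                         within_group_corr = 0.9, noise_sd = 0.1,
                         detection_corr = 0.5,
                         scar_label_freq = 1.0, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 10, mean_degree > 0, n_groups >= 1,
            methods_per_group >= 1,
            length(informativeness) == n_groups,
            all(informativeness >= 0 & informativeness <= 1),
            within_group_corr >= 0, within_group_corr <= 1, noise_sd >= 0,
            detection_corr >= 0, detection_corr < 1,
            scar_label_freq > 0, scar_label_freq <= 1)
  if (mean_degree >= n_genes - 1) stop("mean_degree infeasible for n_genes")
  structure(list(n_genes = as.integer(n_genes), topology = topology,
                 mean_degree = mean_degree, n_groups = as.integer(n_groups),
                 methods_per_group = as.integer(methods_per_group),
                 informativeness = informativeness,
                 within_group_corr = within_group_corr, noise_sd = noise_sd,
                 detection_corr = detection_corr,
                 scar_label_freq = scar_label_freq, seed = as.integer(seed)),
            class = "synth_config")
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))

# Background (non-detected) latent scores follow Beta(1, bg_shape):
# bottom-heavy with a light upper tail.
bg_shape <- 3

# Per-row likelihood ratio P(latents | edge) / P(latents | non-edge) for the
# synthetic generator. At shared difficulty z, group g contributes density
# p_g(z)/(1 - a_g) inside its signal window [a_g, 1] plus (1 - p_g(z))
# times the background density; under a non-edge the density is the
# background alone. The detection pattern is mixed over the copula-shared
# difficulty on a fixed Gaussian quadrature grid.
edge_likelihood_ratio <- function(latent, a, rho) {
  G <- length(a)
  N <- nrow(latent)
  zs <- seq(-5, 5, length.out = 61)
  wz <- stats::dnorm(zs); wz <- wz / sum(wz)
  dbg <- matrix(stats::dbeta(latent, 1, bg_shape), N, G)
  inw <- latent >= matrix(a, N, G, byrow = TRUE) - 1e-12
  num <- numeric(N)
  for (k in seq_along(zs)) {
    val <- rep(1, N)
    for (g in seq_len(G)) {
      p <- if (a[g] >= 1) 1 else
        stats::pnorm((stats::qnorm(a[g]) - rho * zs[k]) / sqrt(1 - rho^2))
      win <- if (a[g] >= 1) Inf else p / (1 - a[g])
      val <- val * (ifelse(inw[, g], win, 0) + (1 - p) * dbg[, g])
    }
    num <- num + wz[k] * val
  }
  num / apply(dbg, 1, prod)
}

#' Generate a directed ground-truth network
#'
#' Scale-free networks are grown by directed preferential attachment (new
#' genes are regulated by existing genes chosen preferentially, so early
#' genes become high out-degree hub regulators). Erdos-Renyi networks include
#' each ordered non-self pair independently with probability
#' \code{mean_degree / (2 (n_genes - 1))}, giving the target average total
#' (in + out) degree.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A \code{synth_network}: list with \code{genes} and an \code{edges}
#'   data.frame (\code{regulator}, \code{target}); never contains self-loops.
#' @export
generate_network <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  genes <- gene_names(n)
  if (config$topology == "erdos_renyi") {
    p <- config$mean_degree / (2 * (n - 1))
    grid <- expand.grid(target = seq_len(n), regulator = seq_len(n))
    grid <- grid[grid$regulator != grid$target, ]
    keep <- stats::rbinom(nrow(grid), 1, p) == 1
    edges <- data.frame(regulator = genes[grid$regulator[keep]],
                        target = genes[grid$target[keep]],
                        stringsAsFactors = FALSE)
  } else {
    # per-vertex attachment counts with mean mean_degree / 2, so the total
    # (in + out) degree averages mean_degree
    m_mean <- config$mean_degree / 2
    base <- floor(m_mean)
    extra <- stats::rbinom(n, 1, m_mean - base)
    out_seq <- pmax(base + extra, 0L)
    out_seq[1] <- 0L
    g <- igraph::sample_pa(n, power = 1, out.seq = out_seq, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # sample_pa points new -> old; reverse so hubs regulate later genes
    edges <- data.frame(regulator = genes[el[, 2]], target = genes[el[, 1]],
                        stringsAsFactors = FALSE)
  }
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  edges <- edges[!duplicated(pair_key(edges$regulator, edges$target)), ,
                 drop = FALSE]
  if (nrow(edges) == 0L) stop("generated network has no edges; raise mean_degree")
  structure(list(genes = genes, edges = edges), class = "synth_network")
}

#' Generate base-method score matrices over a network
#'
#' The candidate universe is all ordered non-self gene pairs. Each method
#' group g detects each true edge with probability a_g (the group's
#' informativeness). Undetected edges and all non-edges draw Beta(1, 3)
#' background noise (bottom-heavy with a light upper tail, the shape of
#' real method score distributions in which few non-edges reach top
#' confidence); a detected edge draws its latent from the signal window
#' \code{a_g + (1 - a_g) * Uniform(0, 1)}, so more informative families
#' both detect more edges and place them higher. Groups therefore carry
#' complementary partial information and no single method is a perfect
#' ranker unless a_g = 1 in the noiseless limit.
#' Detection events share a per-edge difficulty through a Gaussian copula
#' (\code{detection_corr}), emulating the empirical tendency of different
#' method families to succeed on the same easy interactions. Each method in
#' a group is the group latent plus private Gaussian noise whose variance
#' is set so methods within a group correlate at about
#' \code{within_group_corr}, plus measurement noise of standard deviation
#' \code{noise_sd}, min-max squashed to [0, 1]; no single method reports
#' its family's latent exactly, so combining a family's redundant methods
#' is genuinely informative, as it is for real relevance-network families
#' (in the noiseless limit \code{within_group_corr = 1, noise_sd = 0} the
#' columns of a group are identical). The Bayes posterior of an edge given
#' the group latents integrates the generative likelihood over the shared
#' difficulty and is returned as the oracle for recovery tests.
#'
#' @param network a \code{synth_network} from \code{\link{generate_network}}.
#' @param config the same \code{\link{synth_config}}.
#' @return A \code{synth_output}: \code{table} (an
#'   \code{\link{interaction_table}}), \code{gold} (an
#'   \code{\link{edge_label_set}} over the table), \code{latent} (N x
#'   n_groups matrix), \code{true_posterior}, \code{group} (method -> group
#'   map), and \code{config}.
#' @export
generate_scores <- function(network, config) {
  set.seed(config$seed + 1L)
  genes <- network$genes
  n <- length(genes)
  grid <- expand.grid(target = genes, regulator = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$regulator != grid$target, ]
  reg <- grid$regulator; tgt <- grid$target
  N <- length(reg)
  keys <- pair_key(reg, tgt)
  y <- as.integer(keys %in% pair_key(network$edges$regulator,
                                     network$edges$target))
  G <- config$n_groups; M <- config$methods_per_group
  a <- config$informativeness
  wc <- config$within_group_corr
  rho <- config$detection_corr
  difficulty <- stats::rnorm(N) # shared across groups: easy edges score low
  latent <- sapply(seq_len(G), function(g) {
    eps <- stats::rnorm(N)
    detected <- (rho * difficulty + sqrt(1 - rho^2) * eps <=
                   stats::qnorm(a[g])) & y == 1
    # detected edges land in the signal window [a_g, 1]; everything else is
    # bottom-heavy background noise
    ifelse(detected, a[g] + (1 - a[g]) * stats::runif(N),
           stats::rbeta(N, 1, bg_shape))
  })
  scores <- matrix(NA_real_, N, G * M)
  for (g in seq_len(G)) {
    # private-noise variance set so cor(method_i, method_j) ~ wc within the
    # group, on top of the configured measurement noise
    corr_var <- if (wc >= 1) 0 else stats::var(latent[, g]) * (1 - wc) / wc
    sd_priv <- sqrt(corr_var + config$noise_sd^2)
    for (m in seq_len(M)) {
      raw <- latent[, g] + stats::rnorm(N, 0, sd_priv)
      scores[, (g - 1) * M + m] <- minmax_unit(raw)
    }
  }
  methods <- paste0("grp", rep(seq_len(G), each = M), "_m",
                    rep(seq_len(M), G))
  # Bayes posterior of an edge given the group latents, from the generative
  # likelihood ratio against the edge prior.
  prior <- mean(y)
  lr <- edge_likelihood_ratio(latent, a, rho)
  post <- ifelse(is.infinite(lr) | is.nan(lr), 1,
                 prior * lr / (prior * lr + (1 - prior)))
  table <- interaction_table(reg, tgt, scores, methods, "none")
  # the constructor sorts rows lexicographically; realign row-wise vectors
  ord <- order(reg, tgt, method = "radix")
  gold <- edge_label_set(which(y[ord] == 1), N)
  structure(list(table = table, gold = gold,
                 latent = latent[ord, , drop = FALSE],
                 true_posterior = post[ord],
                 group = rep(seq_len(G), each = M), config = config),
            class = "synth_output")
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: network plus scores in one call.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A \code{synth_output}; see \code{\link{generate_scores}}.
#' @export
generate_dataset <- function(config) {
  generate_scores(generate_network(config), config)
}

#' Thin a gold standard into SCAR labels
#'
#' Retains each true edge independently with probability \code{label_freq}
#' ("selected completely at random"), producing the labeled subset used by
#' positive-unlabeled recovery experiments. The result may be empty (the
#' cold-start path accepts that).
#'
#' @param gold an \code{\link{edge_label_set}}.
#' @param label_freq retention probability in (0, 1].
#' @param seed RNG seed.
#' @return An \code{\link{edge_label_set}} whose positives are the retained
#'   subset.
#' @export
generate_scar_labels <- function(gold, label_freq, seed) {
  stopifnot(label_freq > 0, label_freq <= 1)
  set.seed(seed)
  keep <- stats::runif(length(gold$positives)) < label_freq
  edge_label_set(gold$positives[keep], gold$n_universe)
}

#' SCAR positive-unlabeled benchmark with a logistic posterior
#'
#' Generates a two-class Gaussian feature model whose Bayes posterior is
#' exactly logistic, then thins the positives into SCAR labels with a known
#' label frequency. Used to test that the ensemble's label-frequency estimate
#' and corrected posterior recover the generative truth.
#'
#' @param n number of examples.
#' @param c_star true label frequency P(labeled | positive).
#' @param seed RNG seed.
#' @param separation mean shift of each feature under the positive class;
#'   larger values make the classes more separable.
#' @param n_features number of features.
#' @param prior positive-class prior.
#' @return List with \code{features} (n x n_features), \code{y} (0/1 truth),
#'   \code{labeled} (indices), \code{posterior} (true P(y = 1 | x)), and
#'   \code{c_star}.
#' @export
simulate_pu_scar <- function(n = 2000L, c_star = 0.5, seed = 1L,
                             separation = 3, n_features = 2L, prior = 0.5) {
  stopifnot(c_star > 0, c_star <= 1, prior > 0, prior < 1)
  set.seed(seed)
  y <- stats::rbinom(n, 1, prior)
  mu <- rep(separation, n_features)
  X <- matrix(stats::rnorm(n * n_features), n, n_features) +
    outer(y, mu)
  # equal-covariance Gaussians => logistic posterior
  eta <- drop(X %*% mu) - sum(mu^2) / 2 + log(prior / (1 - prior))
  posterior <- stats::plogis(eta)
  labeled <- which(y == 1 & stats::runif(n) < c_star)
  list(features = X, y = y, labeled = labeled, posterior = posterior,
       c_star = c_star)
}

#' Write a synthetic dataset as DREAM-style files
#'
#' One TSV prediction file per base method plus a gold-standard file, ready
#' to be read back with \code{\link{read_edge_scores}} and
#' \code{\link{read_gold_standard}}.
#'
#' @param synth a \code{synth_output}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synth_dataset <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- synth$table
  for (k in seq_along(tab$methods))
    write_ranked_predictions(tab$scores[, k], tab,
                             file.path(dir, paste0(tab$methods[k], ".tsv")))
  pos <- synth$gold$positives
  writeLines(sprintf("%s\t%s\t1", tab$regulator[pos], tab$target[pos]),
             file.path(dir, "gold_standard.tsv"))
  invisible(dir)
}
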