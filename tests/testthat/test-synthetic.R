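test_that("erdos-renyi networks hit the target mean total degree", {
  degs <- sapply(1:20, function(sd) {
    net <- generate_network(synth_config(n_genes = 100, mean_degree = 2.42,
                                         topology = "erdos_renyi", seed = sd))
    2 * nrow(net$edges) / 100
  })
  expect_lt(abs(mean(degs) - 2.42) / 2.42, 0.15)
  expect_error(synth_config(n_genes = 10, mean_degree = 20), "infeasible")
})

test_that("scale-free networks have heavier out-degree tails than ER", {
  maxout <- sapply(1:20, function(sd) {
    sf <- generate_network(synth_config(n_genes = 100, mean_degree = 3,
                                        topology = "scale_free", seed = sd))
    er <- generate_network(synth_config(n_genes = 100, mean_degree = 3,
                                        topology = "erdos_renyi", seed = sd))
    c(sf = max(table(sf$edges$regulator)), er = max(table(er$edges$regulator)))
  })
  expect_gt(mean(maxout["sf", ]), mean(maxout["er", ]))
})

test_that("networks never contain self-loops or duplicate edges", {
  for (topo in c("scale_free", "erdos_renyi")) {
    net <- generate_network(synth_config(n_genes = 50, topology = topo,
                                         seed = 4))
    expect_false(any(net$edges$regulator == net$edges$target))
    expect_false(any(duplicated(net$edges)))
  }
})

test_that("datasets are reproducible from (config, seed)", {
  cfg <- synth_config(n_genes = 20, seed = 123)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$table$scores, s2$table$scores)
  expect_identical(s1$gold$positives, s2$gold$positives)
  expect_identical(s1$true_posterior, s2$true_posterior)
})

test_that("fully informative noiseless groups rank all edges first", {
  cfg <- synth_config(n_genes = 20, n_groups = 1, methods_per_group = 3,
                      informativeness = 1, within_group_corr = 1,
                      noise_sd = 0, seed = 5)
  syn <- generate_dataset(cfg)
  lab <- gold_labels(syn$gold, nrow(syn$table$scores), TRUE)
  for (k in 1:3) expect_equal(auroc(syn$table$scores[, k], lab), 1)
  expect_true(all(syn$true_posterior[lab == 1] == 1))
})

test_that("perfect within-group correlation gives identical noiseless columns", {
  cfg <- synth_config(n_genes = 20, n_groups = 2, methods_per_group = 3,
                      informativeness = c(0.8, 0.4), within_group_corr = 1,
                      noise_sd = 0, seed = 6)
  syn <- generate_dataset(cfg)
  expect_equal(syn$table$scores[, 1], syn$table$scores[, 2])
  expect_equal(syn$table$scores[, 4], syn$table$scores[, 6])
  expect_false(isTRUE(all.equal(syn$table$scores[, 1],
                                syn$table$scores[, 4])))
})

test_that("raising informativeness raises a group's expected single-method AUROC", {
  av <- sapply(c(0.3, 0.9), function(a) {
    mean(sapply(1:5, function(sd) {
      cfg <- synth_config(n_genes = 30, n_groups = 1, methods_per_group = 2,
                          informativeness = a, seed = sd)
      syn <- generate_dataset(cfg)
      lab <- gold_labels(syn$gold, nrow(syn$table$scores), TRUE)
      mean(apply(syn$table$scores, 2, function(s) auroc(s, lab)))
    }))
  })
  expect_gt(av[2], av[1])
})

test_that("the generative posterior is a valid probability aligned to the gold", {
  syn <- generate_dataset(synth_config(n_genes = 30, seed = 7))
  expect_true(all(syn$true_posterior >= 0 & syn$true_posterior <= 1))
  lab <- gold_labels(syn$gold, nrow(syn$table$scores), TRUE)
  # the oracle posterior must rank edges far above chance
  expect_gt(auroc(syn$true_posterior, lab), 0.8)
})

test_that("SCAR thinning is binomial and reproducible", {
  gold <- edge_label_set(1:300, 5000)
  counts <- sapply(1:30, function(sd)
    length(generate_scar_labels(gold, 0.5, sd)$positives))
  # 99% binomial interval for Binomial(300, 0.5)
  expect_true(all(counts >= stats::qbinom(0.005, 300, 0.5) &
                    counts <= stats::qbinom(0.995, 300, 0.5)))
  expect_identical(generate_scar_labels(gold, 0.5, 9)$positives,
                   generate_scar_labels(gold, 0.5, 9)$positives)
  expect_equal(generate_scar_labels(gold, 1, 1)$positives, gold$positives)
})

test_that("scar benchmark exposes the logistic posterior and label frequency", {
  sim <- simulate_pu_scar(n = 500, c_star = 0.7, seed = 8)
  expect_true(all(sim$posterior > 0 & sim$posterior < 1))
  expect_true(all(sim$y[sim$labeled] == 1)) # only positives get labeled
  # labeled fraction of positives near c_star
  expect_equal(length(sim$labeled) / sum(sim$y), 0.7, tolerance = 0.15)
  # the posterior is calibrated: average posterior matches prevalence
  expect_equal(mean(sim$posterior), mean(sim$y), tolerance = 0.05)
})

test_that("datasets round-trip through DREAM-style files", {
  syn <- generate_dataset(synth_config(n_genes = 12, seed = 9))
  dir <- file.path(tempdir(), "synthds")
  write_synth_dataset(syn, dir)
  files <- list.files(dir, pattern = "^grp", full.names = TRUE)
  expect_length(files, 15)
  ms <- lapply(files, read_edge_scores)
  names(ms) <- sub("[.]tsv$", "", basename(files))
  tab <- assemble_feature_table(ms, normalization = "none")
  expect_equal(dim(tab$scores), dim(syn$table$scores))
  gold <- read_gold_standard(file.path(dir, "gold_standard.tsv"), tab)
  expect_equal(length(gold$positives), length(syn$gold$positives))
})
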