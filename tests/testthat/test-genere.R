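test_that("label initialization sizes, ties, and gold seeding behave", {
  set.seed(31)
  tab <- make_table(matrix(stats::runif(1000 * 2), 1000, 2))
  L0 <- initialize_labels(tab, NULL, 0.005)
  expect_length(L0, 5) # ceiling(0.005 * 1000)
  gold <- edge_label_set(c(3, 7, 9), 1000)
  expect_equal(initialize_labels(tab, gold, 0.005), c(3, 7, 9))
  # boundary tie: lexicographically smaller pair (lower row index) admitted
  tab2 <- make_table(matrix(c(5, 3, 3, 1), 4, 1))
  expect_equal(initialize_labels(tab2, NULL, 0.5), c(1, 2))
  expect_error(initialize_labels(make_table(matrix(1:4, 4, 1)), NULL, 0),
               "delta too small")
})

test_that("cross-view combination averages the other views", {
  sv <- list(c(0.9, 0.1), c(0.3, 0.5), c(0.6, 0.9))
  expect_equal(combine_other_views(sv, 1), c(0.45, 0.7))
  expect_equal(combine_other_views(sv[1:2], 1), sv[[2]]) # V = 2
  expect_equal(combine_other_views(sv[1], 1), sv[[1]])   # V = 1 degenerate
})

test_that("label updates retract non-seed positives and keep L0 forever", {
  combined <- c(0.1, 0.9, 0.8, 0.2, 0.05)
  L0 <- c(5L)
  upd <- update_labeled_set(combined, delta = 0.4, L0 = L0)
  expect_equal(upd, c(2L, 3L, 5L)) # top-2 plus permanent seed
  # a previously promoted index (say 1) outside both top set and L0 is gone
  expect_false(1L %in% upd)
  # when the top set covers L0 the size is exactly ceiling(delta * N)
  upd2 <- update_labeled_set(c(1, 0.9, 0, 0, 0), delta = 0.4, L0 = 1L)
  expect_length(upd2, 2)
})

test_that("the 1VI special case matches run_genere(V = 1, max_iter = 1) bit-for-bit", {
  for (sd in 1:3) {
    syn <- generate_dataset(synth_config(n_genes = 20, seed = sd))
    cfg <- genere_config(V = 1, max_iter = 1, seed = 50 + sd,
                         cold_start = TRUE, classifier = "logistic",
                         max_W = 100)
    fit <- suppressWarnings(run_genere(syn$table, cfg))
    f1vi <- suppressWarnings(run_1vi(syn$table, delta = cfg$delta,
                                     gamma = cfg$gamma, max_W = 100,
                                     classifier = "logistic",
                                     seed = 50 + sd, cold_start = TRUE))
    expect_identical(fit$scores, pmin(f1vi, 1))
  }
})

test_that("extending max_iter never changes earlier rounds (prefix determinism)", {
  syn <- generate_dataset(synth_config(n_genes = 20, seed = 33))
  cfg1 <- genere_config(V = 2, max_iter = 1, seed = 77, cold_start = TRUE,
                        classifier = "logistic", max_W = 100)
  cfg2 <- genere_config(V = 2, max_iter = 2, seed = 77, cold_start = TRUE,
                        classifier = "logistic", max_W = 100)
  f1 <- suppressWarnings(run_genere(syn$table, cfg1))
  f2 <- suppressWarnings(run_genere(syn$table, cfg2))
  expect_identical(f1$iterations[[1]]$scores, f2$iterations[[1]]$scores)
  expect_identical(f1$iterations[[1]]$next_label_sizes,
                   f2$iterations[[1]]$next_label_sizes)
})

test_that("structural invariants hold on every run", {
  syn <- generate_dataset(synth_config(n_genes = 25, seed = 34))
  N <- nrow(syn$table$scores)
  cfg <- genere_config(V = 3, max_iter = 3, delta = 0.004, seed = 21,
                       cold_start = TRUE, classifier = "logistic",
                       max_W = 100)
  fit <- suppressWarnings(run_genere(syn$table, cfg, gold = syn$gold))
  kmax <- ceiling(cfg$delta * N) + length(fit$L0)
  for (it in fit$iterations) {
    expect_true(all(it$scores >= 0 & it$scores <= 1))
    expect_true(all(it$label_sizes <= kmax))
    expect_true(all(it$label_sizes >= length(fit$L0)))
  }
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # L0 permanence: recompute the final label sets and check containment
  expect_true(all(fit$iterations[[3]]$next_label_sizes >= length(fit$L0)))
})

test_that("noisy promotions are retracted at later rounds", {
  # weakly informative families make early promotions unreliable, so some
  # promoted interaction outside L0 must drop out again
  syn <- generate_dataset(synth_config(
    n_genes = 25, informativeness = c(0.5, 0.35, 0.2), seed = 35))
  cfg <- genere_config(V = 2, max_iter = 4, delta = 0.008, seed = 13,
                       cold_start = TRUE, classifier = "logistic",
                       max_W = 100)
  fit <- suppressWarnings(run_genere(syn$table, cfg))
  removed <- sum(vapply(fit$iterations, function(it)
    sum(it$churn_removed), numeric(1)))
  expect_gt(removed, 0)
  # and L0 itself is never retracted: sizes never fall below |L0|
  expect_true(all(vapply(fit$iterations, function(it)
    min(it$next_label_sizes), numeric(1)) >= length(fit$L0)))
})

test_that("gold seeding is bypassed under cold start", {
  syn <- generate_dataset(synth_config(n_genes = 20, seed = 36))
  cfg_cold <- genere_config(V = 1, max_iter = 1, seed = 9, cold_start = TRUE,
                            classifier = "logistic", max_W = 50)
  fit <- suppressWarnings(run_genere(syn$table, cfg_cold, gold = syn$gold))
  expect_equal(fit$L0, initialize_labels(syn$table, NULL, cfg_cold$delta))
  cfg_warm <- genere_config(V = 1, max_iter = 1, seed = 9, cold_start = FALSE,
                            classifier = "logistic", max_W = 50)
  fit2 <- suppressWarnings(run_genere(syn$table, cfg_warm, gold = syn$gold))
  expect_equal(fit2$L0, syn$gold$positives)
})

test_that("run configurations validate their arguments", {
  expect_error(genere_config(V = 0), "V >= 1")
  expect_error(genere_config(delta = 0), "delta > 0")
  expect_error(genere_config(max_iter = 0), "max_iter")
  expect_error(genere_config(gamma = 1), "gamma < 1")
})
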