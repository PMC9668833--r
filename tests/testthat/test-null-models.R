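test_that("gene shuffling preserves sizes, categories and determinism", {
  dgm <- make_map(list(D1 = c("A", "B", "C"), D2 = c("B", "D"), D3 = "E"),
                  category = c("cardiovascular", "metabolic", "nervous"))
  for (s in 1:25) {
    sh <- shuffle_disease_genes(dgm, s)
    expect_equal(lengths(sh$genes), lengths(dgm$genes))
    expect_equal(sh$category, dgm$category)
    pool <- unique(unlist(dgm$genes))
    expect_true(all(unlist(sh$genes) %in% pool))
    expect_true(all(vapply(sh$genes, anyDuplicated, integer(1)) == 0L))
  }
  expect_identical(shuffle_disease_genes(dgm, 99),
                   shuffle_disease_genes(dgm, 99))

  # single-disease map: the pool is the disease itself
  one <- make_map(list(D1 = c("A", "B")))
  expect_setequal(shuffle_disease_genes(one, 3)$genes$D1, c("A", "B"))
})

test_that("degree-preserving shuffle keeps each gene's disease multiplicity", {
  dgm <- make_map(list(D1 = c("A", "B", "C"), D2 = c("A", "D"),
                       D3 = c("A", "B", "E", "F")))
  sh <- shuffle_disease_genes(dgm, 5, preserve_gene_degree = TRUE)
  # multiset of genes over all diseases is preserved up to within-disease
  # collision collapses
  orig <- sort(unlist(dgm$genes, use.names = FALSE))
  new <- sort(unlist(sh$genes, use.names = FALSE))
  expect_true(length(new) <= length(orig))
  expect_true(all(new %in% orig))
})

test_that("z-score arithmetic and degenerate nulls are reported correctly", {
  s <- diseasome:::null_summary("x", real = 10, null_values = c(2, 4, 6),
                                n_trials = 3, seed = 1)
  expect_equal(s$z_score, (10 - 4) / 2)
  expect_equal(s$p_value, stats::pnorm(3, lower.tail = FALSE))
  expect_equal(s$fold_change, 2.5)

  deg <- diseasome:::null_summary("x", 5, rep(5, 10), 10, 1)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$z_score))
})

test_that("observed link count beats the null on planted coherent structure", {
  # an anchor family of diseases sharing genes from a small private pool,
  # plus singleton padding diseases that enlarge the shuffle pool so a
  # random reassignment rarely reproduces the concentrated sharing
  family_pool <- sprintf("A%02d", 1:6)
  family <- withr::with_seed(41, stats::setNames(
    lapply(1:8, function(i) sample(family_pool, 3)),
    sprintf("F%d", 1:8)))
  padding <- stats::setNames(as.list(sprintf("U%02d", 1:40)),
                             sprintf("P%02d", 1:40))
  dgm <- make_map(c(family, padding))
  res <- null_link_significance(dgm, family_pool, n_trials = 300, seed = 4)
  expect_gt(res$z_score, 2)
  expect_equal(res$n_trials, 300L)
  expect_equal(res$seed, 4)
  # exact reproducibility from the recorded seed
  res2 <- null_link_significance(dgm, family_pool, n_trials = 300, seed = 4)
  expect_identical(null_summary_table(res), null_summary_table(res2))
})

test_that("null mean and sd stabilize as trials grow", {
  cfg <- synthetic_config(n_diseases = 15, n_genes = 150, n_pathways = 5,
                          pathway_size = c(10, 15), disease_size = c(2, 6),
                          coherence = 0.7, n_nodes = 50, module_size = 10,
                          seed = 8)
  dgm <- disease_gene_map(generate_disease_gene_data(cfg)$table)
  anchor <- unique(unlist(dgm$genes))[1:10]
  a <- null_link_significance(dgm, anchor, n_trials = 400, seed = 1)
  b <- null_link_significance(dgm, anchor, n_trials = 800, seed = 2)
  expect_lt(abs(a$null_mean - b$null_mean) / b$null_mean, 0.05)
  expect_lt(abs(a$null_sd - b$null_sd) / b$null_sd, 0.25)
})

test_that("intra-category link counts follow category structure", {
  # all diseases share one category: intra count = all links
  same <- make_map(list(D1 = c("A", "B"), D2 = c("B", "C"), D3 = c("C", "A")))
  d <- project(build_bipartite(as_disease_gene_table(same)))
  counts <- intra_category_links(d)
  expect_equal(unname(counts["cardiovascular"]), igraph::ecount(d))

  # alternating categories on a single-link map: intra count 0
  alt <- make_map(list(D1 = "A", D2 = "A"),
                  category = c("cardiovascular", "metabolic"))
  d2 <- project(build_bipartite(as_disease_gene_table(alt)))
  expect_equal(sum(intra_category_links(d2)), 0L)
})

test_that("planted within-category sharing yields significant intra-category z", {
  # two planted categories drawing from small category-private pools, plus
  # singleton padding diseases that enlarge the shuffle pool so random
  # sharing is rare
  pool1 <- sprintf("A%02d", 1:4)
  pool2 <- sprintf("B%02d", 1:4)
  planted <- withr::with_seed(31, c(
    stats::setNames(lapply(1:4, function(i) sample(pool1, 3)),
                    sprintf("C1_%d", 1:4)),
    stats::setNames(lapply(1:4, function(i) sample(pool2, 3)),
                    sprintf("C2_%d", 1:4))))
  padding <- stats::setNames(as.list(sprintf("U%02d", 1:30)),
                             sprintf("P%02d", 1:30))
  dgm <- make_map(c(planted, padding),
                  category = c(rep("cardiovascular", 4), rep("metabolic", 4),
                               rep("nervous", 30)))
  anchor <- c(pool1, pool2)
  res <- intra_category_significance(dgm, anchor, n_trials = 1000, seed = 12)
  expect_gt(res[["cardiovascular"]]$z_score, 2)
  expect_gt(res[["metabolic"]]$z_score, 2)
})
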