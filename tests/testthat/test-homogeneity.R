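sets3 <- gene_set_collection(list(P1 = c("G1", "G2"), P2 = "G3"))

test_that("homogeneity score is the best-set fraction of annotated genes", {
  s1 <- homogeneity_score("G1", gene_set_collection(list(P1 = "G1")))
  expect_equal(s1$ph, 1)
  expect_equal(s1$n_i, 1L)

  s2 <- homogeneity_score(c("G1", "G2", "G3"), sets3)
  expect_equal(s2$n_i, 3L)
  expect_equal(s2$best_set_id, "P1")
  expect_equal(s2$ph, 2 / 3)

  s3 <- homogeneity_score(c("G1", "G2"), gene_set_collection(list(P1 = "G9")))
  expect_false(s3$defined)
  expect_true(is.na(s3$ph))

  expect_error(homogeneity_score(character(0), sets3), "non-empty")
})

test_that("homogeneity is invariant to gene order and duplicated set entries", {
  g <- c("G1", "G2", "G3")
  a <- homogeneity_score(g, sets3)$ph
  b <- homogeneity_score(rev(g), sets3)$ph
  expect_equal(a, b)
  dup <- gene_set_collection(list(P1 = c("G1", "G2", "G2", "G1"), P2 = "G3"))
  expect_equal(homogeneity_score(g, dup)$ph, a)
})

test_that("adding sets raises the score whenever the annotated count is unchanged", {
  # the max in PH runs over a larger index set, so for a fixed annotated
  # gene count n_i the score cannot decrease; when extra sets annotate new
  # genes the denominator grows and the comparison is not meaningful
  genes <- withr::with_seed(2, replicate(25, sample(sprintf("G%02d", 1:30),
                                                    sample(3:8, 1)),
                                         simplify = FALSE))
  all_sets <- withr::with_seed(3, gene_set_collection(stats::setNames(
    lapply(1:8, function(i) sample(sprintf("G%02d", 1:30), 10)),
    sprintf("P%d", 1:8))))
  sub_sets <- gene_set_collection(unclass(all_sets)[1:4])
  compared <- 0L
  for (g in genes) {
    full <- homogeneity_score(g, all_sets)
    sub <- homogeneity_score(g, sub_sets)
    if (sub$defined && full$defined && full$n_i == sub$n_i) {
      expect_gte(full$ph, sub$ph)
      compared <- compared + 1L
    }
  }
  expect_gt(compared, 0L)
})

test_that("profiles score every annotated disease and normalize the histogram", {
  dgm <- make_map(list(D1 = c("G1", "G2"), D2 = "G3", D3 = "ZZ"))
  prof <- homogeneity_profile(dgm, sets3)
  expect_equal(sort(prof$scores$disease_id), c("D1", "D2"))  # D3 unannotated
  expect_true(all(prof$scores$ph == 1))
  expect_equal(sum(prof$histogram$frequency), 1)

  # diseases drawn from a single set are all perfectly homogeneous
  one <- gene_set_collection(list(P = sprintf("G%02d", 1:10)))
  dgm2 <- make_map(list(A = c("G01", "G02"), B = c("G03", "G04", "G05")))
  expect_true(all(homogeneity_profile(dgm2, one)$scores$ph == 1))

  expect_error(homogeneity_profile(make_map(list(D = "ZZ")), sets3),
               "no disease")
})

test_that("per-aspect GO runs use only that aspect's annotations", {
  ann <- data.frame(gene = c("G1", "G2", "G1"),
                    aspect = c("BP", "BP", "MF"),
                    term = c("T1", "T1", "T2"))
  bp <- go_gene_sets(ann, "BP")
  mf <- go_gene_sets(ann, "MF")
  expect_equal(homogeneity_score(c("G1", "G2"), bp)$n_i, 2L)
  expect_equal(homogeneity_score(c("G1", "G2"), mf)$n_i, 1L)
  expect_error(go_gene_sets(ann, "CC"), "CC")
})

test_that("the z-score equals a direct recomputation on frozen trials", {
  dgm <- make_map(list(D1 = c("G1", "G2"), D2 = c("G1", "G3"),
                       D3 = c("G2", "G3", "G4")))
  sets <- gene_set_collection(list(P1 = c("G1", "G2", "G4"),
                                   P2 = c("G3", "G4")))
  res <- perfect_homogeneity_test(dgm, sets, n_trials = 300, seed = 17)
  # brute-force recomputation of the same statistic with the same seed
  idx <- gene_set_index(sets)
  universe <- sort(names(idx))
  ph_of <- function(g) {
    ann <- g[g %in% names(idx)]
    counts <- table(unlist(idx[ann]))
    max(counts) / length(ann)
  }
  real <- sum(vapply(dgm$genes, ph_of, numeric(1)) == 1)
  sizes <- vapply(dgm$genes, function(g) sum(g %in% names(idx)), integer(1))
  nulls <- withr::with_seed(17, vapply(1:300, function(t) {
    sum(vapply(sizes, function(sz) ph_of(sample(names(idx), sz)) == 1,
               logical(1)))
  }, numeric(1)))
  expect_equal(res$real, real)
  expect_equal(res$z_score, (real - mean(nulls)) / stats::sd(nulls))
})

test_that("single-gene diseases make the perfect-homogeneity null degenerate", {
  dgm <- make_map(list(D1 = "G1", D2 = "G2"))
  sets <- gene_set_collection(list(P1 = c("G1", "G2")))
  res <- perfect_homogeneity_test(dgm, sets, n_trials = 100, seed = 2)
  expect_true(res$degenerate)
  expect_equal(res$real, 2)
  expect_equal(res$null_mean, 2)
})

test_that("coherent planted maps give large z against the incoherent null", {
  cfg <- synthetic_config(n_diseases = 30, n_genes = 300, n_pathways = 10,
                          pathway_size = c(10, 15), disease_size = c(2, 8),
                          coherence = 1, n_nodes = 50, module_size = 10,
                          seed = 19)
  dat <- generate_disease_gene_data(cfg)
  res <- perfect_homogeneity_test(disease_gene_map(dat$table), dat$sets,
                                  n_trials = 1000, seed = 3)
  expect_gt(res$z_score, 5)
})

test_that("degree and shared-gene summaries aggregate correctly", {
  dgm <- make_map(list(D1 = c("G1", "G2", "G3"), D2 = c("G1", "G2", "G3")))
  d <- project(build_bipartite(as_disease_gene_table(dgm)))
  scores <- data.frame(disease_id = c("D1", "D2"), ph = c(0.5, 1.0))
  curve <- shared_genes_vs_mean_ph(d, scores)
  expect_equal(curve$shared_genes, 3L)
  expect_equal(curve$mean_ph, 0.75)

  dh <- degree_vs_homogeneity(d, scores)
  expect_equal(nrow(dh), 2L)
  expect_equal(dh$mean_degree, c(1, 1))

  # all scores equal: a single bin holding the global mean degree
  scores2 <- data.frame(disease_id = c("D1", "D2"), ph = c(1, 1))
  dh2 <- degree_vs_homogeneity(d, scores2)
  expect_equal(nrow(dh2), 1L)
  expect_equal(dh2$mean_degree, 1)
})

test_that("high-homogeneity diseases planted with few links give a declining curve", {
  # low-PH diseases share a hub gene (many links); high-PH diseases are
  # pathway-pure and mutually disjoint apart from one link
  low <- stats::setNames(lapply(1:6, function(i) {
    c("HUB", sprintf("PG%02d", 12 + i))
  }), sprintf("L%d", 1:6))
  high <- stats::setNames(lapply(1:4, function(i) {
    sprintf("PG%02d", c(2 * i - 1, 2 * i))
  }), sprintf("H%d", 1:4))
  dgm <- make_map(c(low, high))
  d <- project(build_bipartite(as_disease_gene_table(dgm)))
  sets_all <- gene_set_collection(list(P = sprintf("PG%02d", 1:20),
                                       Q = "HUB"))
  prof <- homogeneity_profile(dgm, sets_all)
  curve <- degree_vs_homogeneity(d, prof$scores, n_bins = 4)
  expect_true(all(diff(curve$mean_degree) <= 0))
})
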