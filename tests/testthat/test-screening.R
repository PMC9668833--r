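test_that("seed enrichment flags the matching set and respects BH ordering", {
  bg <- sprintf("G%03d", 1:100)
  sets <- gene_set_collection(list(HIT = bg[1:8], MISS = bg[51:60],
                                   OTHER = bg[61:80]))
  seeds <- bg[1:8]
  enr <- seed_enrichment(seeds, sets, bg)
  expect_equal(enr$set_id[1], "HIT")
  expect_true(enr$significant[enr$set_id == "HIT"])
  expect_true(all(enr$p_adjusted >= enr$p_value))

  # seeds disjoint from every set: nothing significant
  none <- seed_enrichment(bg[91:95],
                          gene_set_collection(list(A = bg[1:10],
                                                   B = bg[11:20])), bg)
  expect_false(any(none$significant))

  expect_error(seed_enrichment(seeds, sets, character(0)), "empty background")
})

test_that("Fisher one-sided p equals the explicit hypergeometric tail sum", {
  cases <- list(c(3, 7, 10, 180), c(5, 5, 20, 70), c(1, 9, 50, 40),
                c(0, 10, 10, 80))
  for (tc in cases) {
    ft <- stats::fisher.test(matrix(c(tc[1], tc[3], tc[2], tc[4]), nrow = 2),
                             alternative = "greater")$p.value
    expect_equal(ft, brute_fisher_greater(tc[1], tc[2], tc[3], tc[4]),
                 tolerance = 1e-10)
    # and equals the connectivity p-value under the argument mapping
    N <- sum(tc)
    expect_equal(ft, connectivity_pvalue(tc[1] + tc[3], tc[1], N,
                                         tc[1] + tc[2]),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition", {
  p <- withr::with_seed(8, stats::runif(200)^2)
  expect_lt(max(abs(stats::p.adjust(p, "BH") - brute_bh(p))), 1e-12)
})

test_that("window boundary stops at the first failing window", {
  bg <- sprintf("G%04d", 1:500)
  universe <- bg[1:40]
  # ranking entirely inside a small universe: every window passes
  ranking <- universe[1:30]
  b <- sliding_window_boundary(ranking, universe, w = 10, background = bg)
  expect_equal(b$boundary, 30L)
  expect_equal(b$accepted, ranking)

  # first window already non-significant: boundary 0
  b0 <- sliding_window_boundary(bg[301:340], universe, w = 10,
                                background = bg)
  expect_equal(b0$boundary, 0L)
  expect_equal(length(b0$accepted), 0L)

  expect_error(sliding_window_boundary(bg[1:5], universe, w = 10,
                                       background = bg), "shorter")
})

test_that("boundary modes and stride behave as documented", {
  bg <- sprintf("G%04d", 1:400)
  universe <- bg[1:60]
  # pass run, then failures, then (by construction) a late passing window
  ranking <- c(universe[1:30], bg[200:239], universe[31:50])
  first <- sliding_window_boundary(ranking, universe, w = 15, background = bg)
  last <- sliding_window_boundary(ranking, universe, w = 15, background = bg,
                                  mode = "last_pass")
  expect_lt(first$boundary, last$boundary)
  strided <- sliding_window_boundary(ranking, universe, w = 15,
                                     background = bg, stride = 5)
  expect_true(all(diff(strided$windows$start) == 5))
})

test_that("true hits are exactly the members of seed-significant sets", {
  bg <- sprintf("G%03d", 1:100)
  sets <- gene_set_collection(list(HIT = bg[1:10], COLD = bg[41:50]))
  enr <- seed_enrichment(bg[1:8], sets, bg)
  universe <- enriched_gene_universe(enr, sets)
  flags <- flag_true_hits(c(bg[9], bg[45], bg[99]), universe)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE))
  # no significant sets: all false
  none <- enriched_gene_universe(seed_enrichment(bg[90:92], sets, bg), sets)
  expect_false(any(flag_true_hits(bg[1:10], none)))
})

fixture_tables <- function() {
  screen_tables(
    orthologs = data.frame(
      mouse_gene = c("m-nos3", "m-mmp2", "m-sirt1", "m-cav1"),
      human_gene = c("NOS3", "MMP2", "SIRT1", "CAV1")),
    heart_phenotype_genes = c("m-nos3", "m-mmp2"),
    expression = data.frame(
      gene = c("NOS3", "MMP2", "SIRT1", "NOS3"),
      tissue = c("heart_muscle", "heart_muscle", "heart_muscle", "brain"),
      ptpm = c(2.5, 2.0, 10, 0.1)))
}

test_that("mouse phenotype screen keeps only abnormal-heart orthologs", {
  tb <- fixture_tables()
  expect_setequal(mouse_phenotype_screen(c("NOS3", "MMP2", "SIRT1", "XXX"), tb),
                  c("NOS3", "MMP2"))
  # SIRT1's ortholog exists but carries no heart phenotype: dropped
  expect_equal(mouse_phenotype_screen("SIRT1", tb), character(0))
  expect_equal(mouse_phenotype_screen(character(0), tb), character(0))
  empty <- screen_tables(data.frame(mouse_gene = character(0),
                                    human_gene = character(0)),
                         character(0), tb$expression)
  expect_warning(out <- mouse_phenotype_screen("NOS3", empty), "empty ortholog")
  expect_equal(out, character(0))
})

test_that("expression screen applies the strict pTPM cut-off", {
  tb <- fixture_tables()
  expect_equal(expression_screen("NOS3", tb, "heart_muscle"), "NOS3")   # 2.5
  expect_equal(expression_screen("MMP2", tb, "heart_muscle"),
               character(0))                                            # 2.0
  expect_message(out <- expression_screen(c("SIRT1", "ABSENT"), tb,
                                          "heart_muscle"), "absent")
  expect_equal(out, "SIRT1")
  expect_error(expression_screen("NOS3", tb, "kidney"), "available")
})

test_that("screens are monotone in the candidate set", {
  tb <- fixture_tables()
  small <- c("NOS3")
  large <- c("NOS3", "MMP2", "SIRT1")
  expect_true(all(mouse_phenotype_screen(small, tb) %in%
                    mouse_phenotype_screen(large, tb)))
  expect_true(all(expression_screen(small, tb, "heart_muscle") %in%
                    expression_screen(large, tb, "heart_muscle")))
})

test_that("new links are attributed to the candidates that create them", {
  dgm <- make_map(list(A = "G1", B = "G2", C = "G3"))
  out <- new_disease_links(dgm, "A", c("G2", "G3"))
  expect_equal(nrow(out$links), 2L)
  expect_equal(unname(out$contribution), c(50, 50))

  # candidate already in the anchor set contributes nothing
  out2 <- new_disease_links(dgm, "A", "G1")
  expect_equal(nrow(out2$links), 0L)

  # one candidate linking one previously unlinked disease: 100%
  out3 <- new_disease_links(dgm, "A", "G2")
  expect_equal(out3$links$disease, "B")
  expect_equal(unname(out3$contribution), 100)

  # diseases already linked to the anchor are not re-counted
  dgm2 <- make_map(list(A = c("G1", "G2"), B = c("G2", "G9"), C = "G3"))
  out4 <- new_disease_links(dgm2, "A", c("G9", "G3"))
  expect_equal(out4$links$disease, "C")
})
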