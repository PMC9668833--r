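#' Run the full diseasome pipeline on an input bundle
#'
#' Executes the stages in order — bipartite construction and anchor
#' restriction, diseasome projection and network statistics, permutation
#' null models, pathway homogeneity, DIAMOnD expansion from the seed
#' genes, sliding-window boundary, mouse-phenotype and expression
#' screening, and new-link attribution — writing every stage output plus a
#' run manifest (parameters, seeds, per-file MD5 checksums) to `out_dir`.
#' Every stage is also an exported function runnable on its own
#' intermediate files; the pipeline holds no hidden state.
#'
#' @param inputs named list of input paths as produced by
#'   [simulate_inputs()] (`disease_gene`, `pathways`, `interactome`,
#'   `seeds`, `orthologs`, `heart_phenotype`, `expression`), or a
#'   directory containing files with those default names.
#' @param out_dir output directory (created).
#' @param anchor_genes anchor gene set; defaults to the seed genes.
#' @param anchor_disease disease whose new links are attributed; defaults
#'   to the disease sharing most genes with the anchor set.
#' @param n_trials permutation trials for the null models (default 1000).
#' @param diamond_iterations DIAMOnD expansion length (default 1000).
#' @param window_stride stride of the sliding boundary window (default 1).
#' @param alpha significance level for enrichment and boundary
#'   (default 0.05).
#' @param tissue tissue used for the expression screen
#'   (default "heart_muscle").
#' @param seed master seed; stage seeds are derived from it and recorded
#'   in the manifest.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(inputs, out_dir,
                         anchor_genes = NULL, anchor_disease = NULL,
                         n_trials = 1000, diamond_iterations = 1000,
                         window_stride = 1, alpha = 0.05,
                         tissue = "heart_muscle", seed = 1L) {
  if (is.character(inputs) && length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list(
      disease_gene = file.path(inputs, "disease_gene.tsv"),
      pathways = file.path(inputs, "pathways.gmt"),
      interactome = file.path(inputs, "interactome.tsv"),
      seeds = file.path(inputs, "seed_genes.txt"),
      orthologs = file.path(inputs, "orthologs.tsv"),
      heart_phenotype = file.path(inputs, "heart_phenotype_genes.txt"),
      expression = file.path(inputs, "expression.tsv"))
  }
  needed <- c("disease_gene", "pathways", "interactome", "seeds",
              "orthologs", "heart_phenotype", "expression")
  for (nm in needed) {
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]])) {
      stop(sprintf("pipeline stage 'inputs': missing input '%s'", nm),
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- list(null = seed + 1L, intra = seed + 2L, homogeneity = seed + 3L)

  table <- stage("io", suppressMessages(read_disease_gene_table(
    inputs$disease_gene)))
  sets <- stage("io", read_gmt(inputs$pathways))
  interactome_el <- stage("io", suppressMessages(read_edge_list(
    inputs$interactome)))
  seed_genes <- stage("io", read_gene_list(inputs$seeds))
  tables <- stage("io", screen_tables(
    read_ortholog_table(inputs$orthologs),
    read_gene_list(inputs$heart_phenotype),
    read_expression_table(inputs$expression)))
  if (is.null(anchor_genes)) anchor_genes <- seed_genes

  dgm <- stage("diseasome", disease_gene_map(table))
  bn <- stage("diseasome", build_bipartite(table))
  bn_anchor <- stage("diseasome", restrict_to_anchor(bn, anchor_genes))
  d <- stage("diseasome", project(bn_anchor))
  write_diseasome(d, file.path(out_dir, "diseasome_edges.tsv"),
                  file.path(out_dir, "diseasome_nodes.tsv"))

  stats_out <- stage("network_stats", diseasome_stats(d))
  utils::write.table(stats_out$centralities,
                     file.path(out_dir, "centralities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nulls <- stage("null_models", null_link_significance(
    dgm, anchor_genes, n_trials = n_trials, seed = seeds$null))
  intra <- stage("null_models", intra_category_significance(
    dgm, anchor_genes, n_trials = n_trials, seed = seeds$intra))
  jsonlite::write_json(
    list(link_significance = unclass(nulls),
         intra_category = lapply(intra, unclass)),
    file.path(out_dir, "null_models.json"), auto_unbox = TRUE, digits = NA)

  hom <- stage("homogeneity", homogeneity_profile(dgm, sets))
  pht <- stage("homogeneity", perfect_homogeneity_test(
    dgm, sets, n_trials = n_trials, seed = seeds$homogeneity))
  utils::write.table(hom$scores, file.path(out_dir, "homogeneity_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(pht), file.path(out_dir, "homogeneity_test.json"),
                       auto_unbox = TRUE, digits = NA)

  graph <- stage("diamond", igraph::graph_from_data_frame(
    interactome_el[, 1:2], directed = FALSE))
  ranking <- stage("diamond", diamond_rank(graph, seed_genes,
                                           n_iterations = diamond_iterations))
  write_diamond_ranking(ranking, file.path(out_dir, "diamond_ranking.tsv"))

  background <- stage("screening", intersect(
    igraph::V(graph)$name, unique(unlist(unclass(sets), use.names = FALSE))))
  enr <- stage("screening", seed_enrichment(seed_genes, sets, background,
                                            alpha = alpha))
  universe <- enriched_gene_universe(enr, sets)
  boundary <- stage("screening", sliding_window_boundary(
    ranking, universe, w = max(length(intersect(seed_genes, background)), 2L),
    background = background, alpha = alpha, stride = window_stride))
  true_hits <- flag_true_hits(ranking, universe)
  mapped <- stage("screening", mouse_phenotype_screen(boundary$accepted,
                                                      tables))
  expressed <- stage("screening", suppressMessages(expression_screen(
    mapped, tables, tissue)))
  candidates <- expressed
  jsonlite::write_json(
    list(w = boundary$w, alpha = boundary$alpha, boundary = boundary$boundary,
         window_p_values = boundary$windows$p_value,
         accepted = boundary$accepted, true_hits = names(true_hits)[true_hits],
         mouse_mapped = mapped, final_candidates = candidates),
    file.path(out_dir, "screening.json"), auto_unbox = TRUE, digits = NA)

  if (is.null(anchor_disease)) {
    overlap <- vapply(dgm$genes, function(g) length(intersect(g, anchor_genes)),
                      integer(1))
    anchor_disease <- names(which.max(overlap))
  }
  links <- stage("links", new_disease_links(dgm, anchor_disease, candidates))
  utils::write.table(links$links, file.path(out_dir, "new_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("diseasome")),
    parameters = list(n_trials = n_trials,
                      diamond_iterations = diamond_iterations,
                      window_stride = window_stride, alpha = alpha,
                      tissue = tissue, anchor_disease = anchor_disease,
                      n_anchor_genes = length(anchor_genes)),
    seeds = c(list(master = seed), seeds),
    outputs = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dgm = dgm, diseasome = d, stats = stats_out,
                 null_links = nulls, intra_category = intra,
                 homogeneity = hom, homogeneity_test = pht,
                 ranking = ranking, enrichment = enr, boundary = boundary,
                 true_hits = true_hits, mouse_mapped = mapped,
                 candidates = candidates, new_links = links,
                 manifest = manifest))
}
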