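#' Configuration for the synthetic input generator
#'
#' One object holds every tunable of the three generators so the whole
#' input bundle is reproducible from a single seed. Defaults emulate, at
#' desk scale, the statistical structure of a curated disease-gene corpus:
#' a few hundred diseases whose heavy-tailed gene sets nearly saturate a
#' shared gene universe (so the pooled-gene shuffle null operates on
#' roughly the same universe the data were drawn from), small dense
#' pathways that make same-pathway disease families share genes heavily,
#' and the planted-module regime used to benchmark module detection: a
#' dense 30-gene module (intra-module edge probability 0.3) on a 400-node
#' background (edge probability 0.02).
#'
#' @param n_diseases number of diseases (default 400).
#' @param n_genes size of the shared gene universe (default 500).
#' @param n_pathways number of pathway gene sets (default 40).
#' @param pathway_size integer range (min, max) of pathway sizes, sampled
#'   uniformly (default c(12, 25)).
#' @param disease_size integer range (min, max) of per-disease gene
#'   counts, sampled from a truncated power law (heavy-tailed, like
#'   real per-disease gene counts; default c(1, 30)).
#' @param disease_size_exponent power-law exponent of disease sizes
#'   (default 1.8).
#' @param coherence probability that a disease gene is drawn from the
#'   disease's home pathway rather than the global pool (default 0.8).
#' @param n_nodes interactome size (default 400).
#' @param p_bg background edge probability (default 0.02).
#' @param p_mod intra-module edge probability (default 0.3).
#' @param module_size planted module size (default 30).
#' @param ortholog_coverage fraction of human genes with a mouse ortholog
#'   (default 0.7).
#' @param heart_rate_true abnormal-heart phenotype rate among designated
#'   true candidates (default 0.5).
#' @param heart_rate_background abnormal-heart rate elsewhere
#'   (default 0.05).
#' @param tissues tissue names for the expression table.
#' @param expr_meanlog,expr_sdlog log-normal pTPM parameters per tissue
#'   (recycled; defaults meanlog 2, sdlog 1, i.e. median pTPM ~ 7.4).
#' @param seed integer RNG seed; identical configs generate byte-identical
#'   bundles.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_diseases = 400, n_genes = 500,
                             n_pathways = 40, pathway_size = c(12, 25),
                             disease_size = c(1, 30),
                             disease_size_exponent = 1.8,
                             coherence = 0.8,
                             n_nodes = 400, p_bg = 0.02, p_mod = 0.3,
                             module_size = 30,
                             ortholog_coverage = 0.7,
                             heart_rate_true = 0.5,
                             heart_rate_background = 0.05,
                             tissues = c("heart_muscle", "brain", "liver"),
                             expr_meanlog = 2, expr_sdlog = 1,
                             seed = 1L) {
  cfg <- list(n_diseases = n_diseases, n_genes = n_genes,
              n_pathways = n_pathways, pathway_size = pathway_size,
              disease_size = disease_size,
              disease_size_exponent = disease_size_exponent,
              coherence = coherence,
              n_nodes = n_nodes, p_bg = p_bg, p_mod = p_mod,
              module_size = module_size,
              ortholog_coverage = ortholog_coverage,
              heart_rate_true = heart_rate_true,
              heart_rate_background = heart_rate_background,
              tissues = tissues,
              expr_meanlog = rep_len(expr_meanlog, length(tissues)),
              expr_sdlog = rep_len(expr_sdlog, length(tissues)),
              seed = as.integer(seed))
  probs <- c(coherence, p_bg, p_mod, ortholog_coverage, heart_rate_true,
             heart_rate_background)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (module_size > n_nodes) stop("module larger than interactome",
                                  call. = FALSE)
  if (n_nodes > n_genes) {
    stop("interactome cannot have more nodes than the gene universe",
         call. = FALSE)
  }
  if (pathway_size[1] < 1 || pathway_size[1] > pathway_size[2] ||
      pathway_size[2] > n_genes) {
    stop("infeasible pathway size range", call. = FALSE)
  }
  if (disease_size[1] < 1 || disease_size[1] > disease_size[2] ||
      disease_size[2] > n_genes) {
    stop("infeasible disease size range", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Shared gene universe: symbols joinable across all three generators.
synthetic_gene_universe <- function(cfg) {
  sprintf("G%05d", seq_len(cfg$n_genes))
}

# Truncated discrete power law P(x) ~ x^-a on [lo, hi].
rtrunc_powerlaw <- function(n, lo, hi, exponent) {
  support <- lo:hi
  sample(support, n, replace = TRUE, prob = support^(-exponent))
}

#' Generate a synthetic disease-gene corpus with planted pathway coherence
#'
#' Builds a pathway collection over the shared gene universe, assigns each
#' disease a home pathway, and draws each disease gene from the home
#' pathway with probability `coherence` (else uniformly from the
#' universe), so the expected pathway homogeneity rises monotonically with
#' the coherence parameter. Categories are assigned round-robin over the
#' twelve organ-system labels. GO-style annotations (aspects BP/MF/CC) are
#' derived from the pathways: each pathway maps to one term per aspect,
#' annotating each member with probability 0.9, so planted coherence
#' carries over to the GO aspects.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `table` (validated disease-gene data.frame), `sets`
#'   (pathway [gene_set_collection()]), `annotations` (data.frame `gene`,
#'   `aspect`, `term`), `home_pathway` (named character).
#' @export
generate_disease_gene_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  universe <- synthetic_gene_universe(cfg)
  withr::with_seed(cfg$seed, {
    sizes_p <- sample(cfg$pathway_size[1]:cfg$pathway_size[2],
                      cfg$n_pathways, replace = TRUE)
    members <- lapply(sizes_p, function(s) sample(universe, s))
    names(members) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    sets <- gene_set_collection(members,
                                rep("synthetic pathway", cfg$n_pathways))
    home <- sprintf("PW%03d",
                    (seq_len(cfg$n_diseases) - 1L) %% cfg$n_pathways + 1L)
    sizes_d <- rtrunc_powerlaw(cfg$n_diseases, cfg$disease_size[1],
                               cfg$disease_size[2],
                               cfg$disease_size_exponent)
    cats <- disease_categories(include_multiple = FALSE)
    disease_ids <- sprintf("D%03d", seq_len(cfg$n_diseases))
    gene_lists <- lapply(seq_len(cfg$n_diseases), function(i) {
      pw <- sets[[home[i]]]
      n <- sizes_d[i]
      n_home <- stats::rbinom(1, n, cfg$coherence)
      n_home <- min(n_home, length(pw))
      g <- sample(pw, n_home)
      extra <- setdiff(universe, g)
      if (n - n_home > 0) g <- c(g, sample(extra, n - n_home))
      g
    })
    table <- data.frame(
      disease_id = rep(disease_ids, lengths(gene_lists)),
      category = rep(cats[(seq_len(cfg$n_diseases) - 1L) %% length(cats) + 1L],
                     lengths(gene_lists)),
      gene = unlist(gene_lists, use.names = FALSE))
    ann <- do.call(rbind, lapply(c("BP", "MF", "CC"), function(aspect) {
      do.call(rbind, lapply(seq_along(sets), function(j) {
        g <- sets[[j]]
        keep <- stats::runif(length(g)) < 0.9
        if (!any(keep)) keep[1] <- TRUE
        data.frame(gene = g[keep], aspect = aspect,
                   term = sprintf("%s%04d", aspect, j))
      }))
    }))
    list(table = suppressMessages(validate_disease_gene_table(table,
                                                              "synthetic")),
         sets = sets, annotations = ann,
         home_pathway = stats::setNames(home, disease_ids))
  })
}

#' Generate a synthetic interactome with a planted module
#'
#' Samples an Erdos-Renyi background (edge probability `p_bg`) over
#' `n_nodes` genes from the shared universe and densifies a planted module
#' (`module_size` genes, edge probability `p_mod`). Returns the graph, the
#' module membership and a random seed subset of the module.
#'
#' @param cfg a [synthetic_config()].
#' @param n_seeds number of module genes returned as seeds (default 10).
#' @param module_genes optional explicit module membership (character
#'   vector, e.g. a pathway's genes); its length overrides
#'   `cfg$module_size`. Extra genes are added to the node set if needed.
#' @return list with `graph` (igraph), `module`, `seeds`.
#' @export
generate_interactome <- function(cfg, n_seeds = 10, module_genes = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  universe <- synthetic_gene_universe(cfg)
  withr::with_seed(cfg$seed + 1L, {
    if (is.null(module_genes)) {
      nodes <- sample(universe, cfg$n_nodes)
      module <- sample(nodes, cfg$module_size)
    } else {
      module <- unique(toupper(module_genes))
      rest <- sample(setdiff(universe, module),
                     max(cfg$n_nodes - length(module), 0))
      nodes <- c(module, rest)
    }
    n <- length(nodes)
    pairs <- utils::combn(n, 2)
    in_mod <- nodes %in% module
    p <- ifelse(in_mod[pairs[1, ]] & in_mod[pairs[2, ]], cfg$p_mod, cfg$p_bg)
    keep <- stats::runif(ncol(pairs)) < p
    el <- data.frame(node_a = nodes[pairs[1, keep]],
                     node_b = nodes[pairs[2, keep]])
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    seeds <- sample(module, min(n_seeds, length(module)))
    list(graph = g, module = module, seeds = seeds)
  })
}

#' Generate synthetic screening tables
#'
#' Mouse orthologs cover a configured fraction of the gene universe (mouse
#' symbol = lower-cased human symbol with an `m-` prefix); abnormal-heart
#' phenotype flags are set at `heart_rate_true` among the designated true
#' candidates and `heart_rate_background` elsewhere; pTPM expression is
#' log-normal per tissue.
#'
#' @param cfg a [synthetic_config()].
#' @param true_candidates character vector of genes the phenotype signal is
#'   enriched on (default none).
#' @param genes gene universe for the tables (default the shared universe).
#' @return a [screen_tables()] object.
#' @export
generate_screening_tables <- function(cfg, true_candidates = character(0),
                                      genes = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(genes)) genes <- synthetic_gene_universe(cfg)
  true_candidates <- unique(toupper(true_candidates))
  withr::with_seed(cfg$seed + 2L, {
    covered <- genes[stats::runif(length(genes)) < cfg$ortholog_coverage |
                       genes %in% true_candidates]
    orthologs <- data.frame(mouse_gene = paste0("m-", tolower(covered)),
                            human_gene = covered)
    rate <- ifelse(covered %in% true_candidates, cfg$heart_rate_true,
                   cfg$heart_rate_background)
    heart <- orthologs$mouse_gene[stats::runif(length(covered)) < rate]
    expression <- do.call(rbind, lapply(seq_along(cfg$tissues), function(t) {
      data.frame(gene = genes, tissue = cfg$tissues[t],
                 ptpm = stats::rlnorm(length(genes), cfg$expr_meanlog[t],
                                      cfg$expr_sdlog[t]))
    }))
    screen_tables(orthologs, heart, expression)
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Generates disease-gene, pathway, GO, interactome, seed, ortholog,
#' phenotype and expression inputs from one config and writes them in the
#' package's file dialects, so the whole pipeline can run from files.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @param n_seeds seed-gene count for the interactome bundle.
#' @return named list of file paths (plus `module` and `seeds` in memory).
#' @export
simulate_inputs <- function(cfg, dir, n_seeds = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- generate_disease_gene_data(cfg)
  net <- generate_interactome(cfg, n_seeds = n_seeds)
  scr <- generate_screening_tables(cfg,
                                   true_candidates = setdiff(net$module,
                                                             net$seeds))
  paths <- list(
    disease_gene = file.path(dir, "disease_gene.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    annotations = file.path(dir, "go_annotations.tsv"),
    interactome = file.path(dir, "interactome.tsv"),
    seeds = file.path(dir, "seed_genes.txt"),
    orthologs = file.path(dir, "orthologs.tsv"),
    heart_phenotype = file.path(dir, "heart_phenotype_genes.txt"),
    expression = file.path(dir, "expression.tsv"),
    config = file.path(dir, "config.json")
  )
  write_disease_gene_table(dat$table, paths$disease_gene)
  write_gmt(dat$sets, paths$pathways)
  utils::write.table(dat$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  names(el)[1:2] <- c("node_a", "node_b")
  write_edge_list(normalize_edge_list(el), paths$interactome)
  writeLines(sort(net$seeds), paths$seeds)
  utils::write.table(scr$orthologs, paths$orthologs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sort(scr$heart_phenotype_genes), paths$heart_phenotype)
  utils::write.table(scr$expression, paths$expression, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA)
  c(paths, list(module = net$module, seeds = net$seeds))
}
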