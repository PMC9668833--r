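#' Resolve a disease's category from per-row votes
#'
#' A disease appearing with a single category keeps it; a strict plurality
#' wins; a tie between the most frequent categories yields `"multiple"`.
#'
#' @param category_votes non-empty character vector of category labels.
#' @return a single category string.
#' @export
#' @examples
#' resolve_category(c("cardiovascular", "cardiovascular", "metabolic"))
#' resolve_category(c("cardiovascular", "metabolic"))
resolve_category <- function(category_votes) {
  if (length(category_votes) == 0L) {
    stop("resolve_category: empty vote list", call. = FALSE)
  }
  tab <- table(category_votes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) top else "multiple"
}

#' Build a disease-gene map from a validated table
#'
#' The map is the pipeline's root container: for each disease, its resolved
#' category and its gene set.
#'
#' @param table validated disease-gene table
#'   (see [validate_disease_gene_table()]).
#' @return object of class `disease_gene_map`: list with elements `genes`
#'   (named list of character vectors) and `category` (named character).
#' @export
disease_gene_map <- function(table) {
  if (nrow(table) == 0L) {
    return(structure(list(genes = list(), category = character(0)),
                     class = "disease_gene_map"))
  }
  genes <- lapply(split(table$gene, table$disease_id), unique)
  category <- vapply(split(table$category, table$disease_id),
                     resolve_category, character(1))
  structure(list(genes = genes, category = category[names(genes)]),
            class = "disease_gene_map")
}

#' @export
print.disease_gene_map <- function(x, ...) {
  cat(sprintf("disease_gene_map: %d diseases, %d distinct genes\n",
              length(x$genes), length(unique(unlist(x$genes, use.names = FALSE)))))
  invisible(x)
}

#' Flatten a disease-gene map back to a table
#'
#' @param dgm a [disease_gene_map()].
#' @return a disease-gene `data.frame` (disease_id, category, gene).
#' @export
as_disease_gene_table <- function(dgm) {
  n <- lengths(dgm$genes)
  data.frame(
    disease_id = rep(names(dgm$genes), n),
    category = rep(unname(dgm$category), n),
    gene = unlist(dgm$genes, use.names = FALSE)
  )
}

#' Build the disease-gene bipartite network
#'
#' One edge per distinct (disease, gene) pair; disease nodes carry their
#' resolved category.
#'
#' @param table validated disease-gene table, or a [disease_gene_map()].
#' @return object of class `bipartite_network`: list with `edges`
#'   (data.frame disease, gene), `diseases`, `genes`, `category`.
#' @export
build_bipartite <- function(table) {
  if (inherits(table, "disease_gene_map")) table <- as_disease_gene_table(table)
  if (nrow(table) == 0L) {
    warning("empty disease-gene table: empty bipartite network", call. = FALSE)
    return(structure(list(
      edges = data.frame(disease = character(0), gene = character(0)),
      diseases = character(0), genes = character(0),
      category = character(0)), class = "bipartite_network"))
  }
  edges <- unique(data.frame(disease = table$disease_id, gene = table$gene))
  rownames(edges) <- NULL
  category <- vapply(split(table$category, table$disease_id),
                     resolve_category, character(1))
  structure(list(edges = edges,
                 diseases = sort(unique(edges$disease)),
                 genes = sort(unique(edges$gene)),
                 category = category),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d diseases, %d genes, %d edges\n",
              length(x$diseases), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Restrict a bipartite network to diseases touching an anchor gene set
#'
#' Keeps exactly the diseases whose gene set intersects `anchor_genes`,
#' retaining ALL of their genes (not only anchor genes); gene nodes left
#' without any disease edge are dropped.
#'
#' @param bn a `bipartite_network`.
#' @param anchor_genes non-empty character vector of gene symbols.
#' @return restricted `bipartite_network`.
#' @export
restrict_to_anchor <- function(bn, anchor_genes) {
  stopifnot(inherits(bn, "bipartite_network"))
  if (length(anchor_genes) == 0L) {
    stop("anchor_genes must be non-empty", call. = FALSE)
  }
  anchor_genes <- toupper(anchor_genes)
  keep_d <- unique(bn$edges$disease[bn$edges$gene %in% anchor_genes])
  if (length(keep_d) == 0L) {
    warning("no disease intersects the anchor gene set", call. = FALSE)
  }
  edges <- bn$edges[bn$edges$disease %in% keep_d, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 diseases = sort(unique(edges$disease)),
                 genes = sort(unique(edges$gene)),
                 category = bn$category[sort(unique(edges$disease))]),
            class = "bipartite_network")
}

# Sparse disease x gene incidence matrix of a bipartite network.
incidence_matrix <- function(bn) {
  d <- factor(bn$edges$disease, levels = bn$diseases)
  g <- factor(bn$edges$gene, levels = bn$genes)
  Matrix::sparseMatrix(i = as.integer(d), j = as.integer(g), x = 1,
                       dims = c(length(bn$diseases), length(bn$genes)),
                       dimnames = list(bn$diseases, bn$genes))
}

#' Project a bipartite network onto disease nodes
#'
#' Two diseases are linked when they share at least one gene; the edge
#' weight is the exact shared-gene count. All diseases of the bipartite
#' network are retained as nodes, including those left without links.
#'
#' @param bn a `bipartite_network`.
#' @return an [igraph::igraph] with vertex attributes `category` and
#'   `gene_count` and integer edge attribute `weight`.
#' @export
project <- function(bn) {
  stopifnot(inherits(bn, "bipartite_network"))
  if (length(bn$diseases) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  M <- incidence_matrix(bn)
  W <- Matrix::tcrossprod(M)
  W <- methods::as(Matrix::triu(W, k = 1), "TsparseMatrix")
  keep <- W@x > 0
  el <- data.frame(from = bn$diseases[W@i[keep] + 1L],
                   to = bn$diseases[W@j[keep] + 1L],
                   weight = as.integer(W@x[keep]))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = bn$diseases))
  cat_attr <- bn$category[igraph::V(g)$name]
  igraph::V(g)$category <- ifelse(is.na(cat_attr), "multiple", unname(cat_attr))
  igraph::V(g)$gene_count <- as.integer(Matrix::rowSums(M))[match(
    igraph::V(g)$name, bn$diseases)]
  g
}

#' Serialize a diseasome
#'
#' Writes a weighted TSV edge list plus a node-attribute TSV
#' (`disease_id`, `category`, `gene_count`).
#'
#' @param d projected diseasome graph.
#' @param edge_path,node_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_diseasome <- function(d, edge_path, node_path) {
  el <- igraph::as_data_frame(d, what = "edges")
  names(el)[1:2] <- c("node_a", "node_b")
  write_edge_list(el, edge_path)
  nodes <- data.frame(disease_id = igraph::V(d)$name,
                      category = igraph::V(d)$category,
                      gene_count = igraph::V(d)$gene_count)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edge_path, nodes = node_path))
}

# Fast edge count of the anchor-restricted projection of a gene-set list.
# Used by the permutation null; avoids igraph construction.
anchor_link_count <- function(genes_list, anchor_genes, per_category = NULL) {
  # category levels fixed from the FULL map so real and trial counts align
  cat_levels <- if (is.null(per_category)) NULL else
    sort(unique(unname(per_category)))
  keep <- vapply(genes_list, function(g) any(g %in% anchor_genes), logical(1))
  genes_list <- genes_list[keep]
  n_d <- length(genes_list)
  if (n_d < 2L) {
    return(list(links = 0L,
                intra = if (is.null(cat_levels)) NULL else
                  stats::setNames(integer(length(cat_levels)), cat_levels),
                diseases = names(genes_list)))
  }
  pool <- unique(unlist(genes_list, use.names = FALSE))
  d <- rep(seq_len(n_d), lengths(genes_list))
  g <- match(unlist(genes_list, use.names = FALSE), pool)
  M <- Matrix::sparseMatrix(i = d, j = g, x = 1,
                            dims = c(n_d, length(pool)))
  W <- methods::as(Matrix::triu(Matrix::tcrossprod(M), k = 1), "TsparseMatrix")
  nz <- W@x > 0
  links <- sum(nz)
  intra <- NULL
  if (!is.null(per_category)) {
    cats <- per_category[names(genes_list)]
    ci <- cats[W@i[nz] + 1L]
    cj <- cats[W@j[nz] + 1L]
    same <- !is.na(ci) & !is.na(cj) & ci == cj
    intra <- table(factor(ci[same], levels = cat_levels))
    intra <- stats::setNames(as.integer(intra), names(intra))
  }
  list(links = links, intra = intra, diseases = names(genes_list))
}
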