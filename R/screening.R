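#' Pathway enrichment of a seed gene set
#'
#' One-sided (enrichment) Fisher's exact test of each gene set against the
#' seed genes over a background universe, with Benjamini-Hochberg
#' correction across all tested sets. The 2x2 table for set S is
#' `[ |seeds & S|, |seeds \ S| ; |(bg \ seeds) & S|, |(bg \ seeds) \ S| ]`,
#' all memberships restricted to the background.
#'
#' @param seeds character vector of seed genes (intersected with the
#'   background).
#' @param sets a [gene_set_collection()].
#' @param background character vector, the gene universe (conventionally
#'   interactome genes intersected with the annotated universe).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return `data.frame` with columns `set_id`, `n_seed_in`, `n_seed_out`,
#'   `n_bg_in`, `n_bg_out`, `odds_ratio`, `p_value`, `p_adjusted`,
#'   `significant`, sorted by p-value; `alpha` stored as an attribute.
#' @export
seed_enrichment <- function(seeds, sets, background, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  background <- unique(toupper(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  seeds <- intersect(unique(toupper(seeds)), background)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    a <- length(intersect(seeds, members))
    b <- length(seeds) - a
    c_ <- length(members) - a
    d <- length(background) - length(seeds) - c_
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2),
                             alternative = "greater")
    data.frame(set_id = id, n_seed_in = a, n_seed_out = b,
               n_bg_in = c_, n_bg_out = d,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Union of member genes of significantly enriched sets
#'
#' @param enrichment result of [seed_enrichment()].
#' @param sets the same [gene_set_collection()].
#' @return character vector of genes belonging to at least one
#'   significantly enriched set.
#' @export
enriched_gene_universe <- function(enrichment, sets) {
  sig <- enrichment$set_id[enrichment$significant]
  unique(unlist(unclass(sets)[sig], use.names = FALSE))
}

#' Flag ranked genes that are "true hits"
#'
#' A ranked gene is a true hit when it belongs to at least one gene set
#' significantly enriched in the seed genes.
#'
#' @param ranking a `diamond_ranking` (or character vector of genes).
#' @param enriched_universe union of genes of seed-significant sets
#'   (see [enriched_gene_universe()]).
#' @return named logical vector along the ranking.
#' @export
flag_true_hits <- function(ranking, enriched_universe) {
  genes <- if (is.character(ranking)) ranking else ranking$gene
  stats::setNames(genes %in% enriched_universe, genes)
}

#' Sliding-window pathway-enrichment boundary of a DIAMOnD ranking
#'
#' Slides a window of `w` consecutively ranked genes (conventionally `w` =
#' number of seed genes) along the ranking and tests each window for
#' enrichment in the seed-enriched pathway gene universe (one-sided
#' Fisher's exact test against the background). The boundary is the end
#' rank of the last window in the initial contiguous run of windows with
#' `p < alpha`; if the first window already fails, the boundary is 0 and
#' no candidate is accepted. `mode = "last_pass"` instead uses the last
#' passing window anywhere in the ranking.
#'
#' @param ranking a `diamond_ranking` or character vector of ranked genes.
#' @param enriched_gene_universe genes of the seed-significant sets.
#' @param w window size (>= 1; ranking must be at least this long).
#' @param background background gene universe.
#' @param alpha p-value cut-off (default 0.05).
#' @param stride ranks between window starts (default 1).
#' @param mode `"first_break"` (default) or `"last_pass"`.
#' @return list of class `boundary_result`: `w`, `alpha`, `stride`,
#'   `windows` (data.frame `start`, `end`, `p_value`), `boundary`
#'   (accepted rank count), `accepted` (character vector of genes).
#' @export
sliding_window_boundary <- function(ranking, enriched_gene_universe, w,
                                    background, alpha = 0.05, stride = 1,
                                    mode = c("first_break", "last_pass")) {
  mode <- match.arg(mode)
  genes <- if (is.character(ranking)) ranking else ranking$gene
  L <- length(genes)
  if (w < 1) stop("window size w must be >= 1", call. = FALSE)
  if (L < w) stop("ranking shorter than the window size", call. = FALSE)
  background <- unique(toupper(background))
  universe <- intersect(unique(toupper(enriched_gene_universe)), background)
  starts <- seq(1L, L - w + 1L, by = stride)
  n_bg <- length(background)
  n_u <- length(universe)
  p <- vapply(starts, function(i) {
    win <- genes[i:(i + w - 1L)]
    win <- intersect(win, background)
    a <- length(intersect(win, universe))
    b <- length(win) - a
    c_ <- n_u - a
    d <- n_bg - length(win) - c_
    stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2),
                       alternative = "greater")$p.value
  }, numeric(1))
  pass <- p < alpha
  if (mode == "first_break") {
    n_pass <- if (!pass[1]) 0L else {
      first_fail <- which(!pass)[1]
      if (is.na(first_fail)) length(pass) else first_fail - 1L
    }
  } else {
    n_pass <- if (any(pass)) max(which(pass)) else 0L
  }
  boundary <- if (n_pass == 0L) 0L else min(starts[n_pass] + w - 1L, L)
  structure(list(w = w, alpha = alpha, stride = stride,
                 windows = data.frame(start = starts,
                                      end = pmin(starts + w - 1L, L),
                                      p_value = p),
                 boundary = boundary,
                 accepted = if (boundary > 0L) genes[seq_len(boundary)]
                            else character(0)),
            class = "boundary_result")
}

#' @export
print.boundary_result <- function(x, ...) {
  cat(sprintf(
    "boundary_result: w = %d, alpha = %g, %d window(s), boundary rank = %d\n",
    x$w, x$alpha, nrow(x$windows), x$boundary))
  invisible(x)
}

#' Bundle of candidate-screening tables
#'
#' @param orthologs `data.frame` (`mouse_gene`, `human_gene`), many-to-one
#'   allowed.
#' @param heart_phenotype_genes character vector of mouse genes with an
#'   abnormal-heart phenotype.
#' @param expression long `data.frame` (`gene`, `tissue`, `ptpm`).
#' @return object of class `screen_tables`.
#' @export
screen_tables <- function(orthologs, heart_phenotype_genes, expression) {
  stopifnot(all(c("mouse_gene", "human_gene") %in% names(orthologs)),
            all(c("gene", "tissue", "ptpm") %in% names(expression)))
  if (any(expression$ptpm < 0)) stop("ptpm values must be >= 0", call. = FALSE)
  structure(list(orthologs = orthologs,
                 heart_phenotype_genes = unique(heart_phenotype_genes),
                 expression = expression),
            class = "screen_tables")
}

#' Screen candidates against abnormal-heart mouse orthologs
#'
#' Keeps the candidates whose human symbol is the ortholog of at least one
#' mouse gene with an abnormal-heart phenotype; candidates whose orthologs
#' carry only non-heart phenotypes are dropped.
#'
#' @param candidates character vector of human gene symbols.
#' @param tables a [screen_tables()].
#' @return character vector, the retained candidates.
#' @export
mouse_phenotype_screen <- function(candidates, tables) {
  stopifnot(inherits(tables, "screen_tables"))
  if (nrow(tables$orthologs) == 0L) {
    warning("empty ortholog map: no candidate can be screened", call. = FALSE)
    return(character(0))
  }
  heart_orthologs <- unique(tables$orthologs$human_gene[
    tables$orthologs$mouse_gene %in% tables$heart_phenotype_genes])
  intersect(unique(toupper(candidates)), heart_orthologs)
}

#' Screen genes by tissue expression
#'
#' Retains genes whose expression in the given tissue exceeds the pTPM
#' cut-off (strictly greater than 2 by default; a gene at exactly the
#' cut-off is dropped). Genes absent from the table are dropped with a log
#' message.
#'
#' @param genes character vector of gene symbols.
#' @param expr long expression `data.frame` (`gene`, `tissue`, `ptpm`) or a
#'   [screen_tables()] object.
#' @param tissue tissue name; unknown tissues raise an error listing the
#'   available ones.
#' @param cutoff strict pTPM threshold (default 2).
#' @return character vector of expressed genes.
#' @export
expression_screen <- function(genes, expr, tissue, cutoff = 2) {
  if (inherits(expr, "screen_tables")) expr <- expr$expression
  tissues <- unique(expr$tissue)
  if (!(tissue %in% tissues)) {
    stop(sprintf("unknown tissue '%s'; available: %s", tissue,
                 paste(sort(tissues), collapse = ", ")), call. = FALSE)
  }
  genes <- unique(toupper(genes))
  sub <- expr[expr$tissue == tissue, , drop = FALSE]
  absent <- setdiff(genes, sub$gene)
  if (length(absent) > 0) {
    message(sprintf("expression_screen: %d gene(s) absent from the table dropped",
                    length(absent)))
  }
  expressed <- unique(sub$gene[sub$ptpm > cutoff])
  intersect(genes, expressed)
}

#' New diseasome links created by candidate genes
#'
#' Augments the anchor disease's gene set with the candidate genes and
#' reports the diseases that become linked to it only through the
#' candidates (no gene shared with the original set), together with each
#' candidate's contribution percentage: the fraction of new links on which
#' that candidate is among the shared genes, times 100. A link crediting
#' several candidates credits each of them.
#'
#' @param dgm a [disease_gene_map()].
#' @param anchor_disease disease id present in `dgm`.
#' @param candidates character vector of candidate genes.
#' @return list with `links` (`data.frame`: `disease`, `shared_candidates`
#'   comma-separated) and `contribution` (named numeric, percent).
#' @export
new_disease_links <- function(dgm, anchor_disease, candidates) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  if (!(anchor_disease %in% names(dgm$genes))) {
    stop(sprintf("anchor disease '%s' not in the map", anchor_disease),
         call. = FALSE)
  }
  original <- dgm$genes[[anchor_disease]]
  candidates <- setdiff(unique(toupper(candidates)), original)
  others <- setdiff(names(dgm$genes), anchor_disease)
  rows <- lapply(others, function(dd) {
    g <- dgm$genes[[dd]]
    if (length(intersect(g, original)) > 0) return(NULL)  # already linked
    shared <- intersect(g, candidates)
    if (length(shared) == 0L) return(NULL)
    data.frame(disease = dd,
               shared_candidates = paste(sort(shared), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(list(links = data.frame(disease = character(0),
                                   shared_candidates = character(0)),
                contribution = stats::setNames(numeric(0), character(0))))
  }
  links <- do.call(rbind, rows)
  rownames(links) <- NULL
  credited <- strsplit(links$shared_candidates, ",", fixed = TRUE)
  tab <- table(unlist(credited))
  contribution <- stats::setNames(100 * as.numeric(tab) / nrow(links),
                                  names(tab))
  contribution <- contribution[order(-contribution, names(contribution))]
  list(links = links, contribution = contribution)
}
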