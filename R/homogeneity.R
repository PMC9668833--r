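#' Invert a gene-set collection to a gene-to-sets index
#'
#' @param sets a [gene_set_collection()].
#' @return named list mapping each annotated gene to the integer indices of
#'   the sets containing it, with the set ids as a `set_ids` attribute.
#' @export
gene_set_index <- function(sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  genes <- unlist(unclass(sets), use.names = FALSE)
  set_of <- rep(seq_along(sets), lengths(sets))
  idx <- split(set_of, genes)
  structure(idx, set_ids = names(sets), class = "gene_set_index")
}

# Core of Eq.-style homogeneity: among the disease's genes annotated to at
# least one set, the largest fraction annotated to a single set.
ph_core <- function(genes, idx) {
  ann <- genes[genes %in% names(idx)]
  n_i <- length(ann)
  if (n_i == 0L) {
    return(list(n_i = 0L, n_ji = NA_integer_, best = NA_character_,
                ph = NA_real_, defined = FALSE))
  }
  counts <- tabulate(unlist(idx[ann], use.names = FALSE),
                     nbins = length(attr(idx, "set_ids")))
  n_ji <- max(counts)
  best <- attr(idx, "set_ids")[which(counts == n_ji)[1]]
  list(n_i = n_i, n_ji = n_ji, best = best, ph = n_ji / n_i, defined = TRUE)
}

#' Pathway / GO homogeneity of a gene set
#'
#' The homogeneity of a disease's gene set with respect to a set
#' collection: with \eqn{n_i} the number of the disease's genes annotated
#' to at least one set and \eqn{n_{ji}} the number annotated to set
#' \eqn{j}, the score is \eqn{PH_i = \max_j (n_{ji} / n_i)}, in (0, 1].
#' Undefined (flagged, not an error) when no gene is annotated.
#'
#' @param genes non-empty character vector of gene symbols.
#' @param sets a [gene_set_collection()] or prebuilt [gene_set_index()].
#' @param disease_id optional label carried into the result.
#' @param aspect tag recorded in the result (`"pathway"`, `"BP"`, `"MF"`,
#'   `"CC"`, ...).
#' @return list with `disease_id`, `n_i`, `n_ji`, `best_set_id`, `ph`,
#'   `defined`, `aspect`.
#' @export
homogeneity_score <- function(genes, sets, disease_id = NA_character_,
                              aspect = "pathway") {
  if (length(genes) == 0L) stop("genes must be non-empty", call. = FALSE)
  idx <- if (inherits(sets, "gene_set_index")) sets else gene_set_index(sets)
  r <- ph_core(unique(toupper(genes)), idx)
  list(disease_id = disease_id, n_i = r$n_i, n_ji = r$n_ji,
       best_set_id = r$best, ph = r$ph, defined = r$defined, aspect = aspect)
}

#' Homogeneity profile of a disease-gene map
#'
#' One homogeneity score per disease with at least one annotated gene,
#' plus a normalized histogram of the scores over (0, 1].
#'
#' @param dgm a [disease_gene_map()].
#' @param sets a [gene_set_collection()] (pathways, or one GO aspect's term
#'   memberships; see [go_gene_sets()]).
#' @param aspect tag recorded on each score.
#' @param n_bins histogram bin count over \[0, 1\] (default 10).
#' @return list with `scores` (data.frame: disease_id, n_i, n_ji,
#'   best_set_id, ph, aspect) and `histogram` (data.frame: bin_low,
#'   bin_high, count, frequency).
#' @export
homogeneity_profile <- function(dgm, sets, aspect = "pathway", n_bins = 10) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  idx <- if (inherits(sets, "gene_set_index")) sets else gene_set_index(sets)
  rows <- lapply(names(dgm$genes), function(d) {
    r <- ph_core(dgm$genes[[d]], idx)
    if (!r$defined) return(NULL)
    data.frame(disease_id = d, n_i = r$n_i, n_ji = r$n_ji,
               best_set_id = r$best, ph = r$ph, aspect = aspect)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no disease has any annotated gene", call. = FALSE)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  breaks <- seq(0, 1, length.out = n_bins + 1)
  cnt <- tabulate(cut(scores$ph, breaks, include.lowest = FALSE,
                      labels = FALSE), nbins = n_bins)
  histogram <- data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1],
                          count = cnt,
                          frequency = cnt / sum(cnt))
  list(scores = scores, histogram = histogram)
}

#' Build one GO aspect's gene sets from a flat annotation table
#'
#' @param annotations `data.frame` with columns `gene`, `aspect`, `term`.
#' @param aspect one of the aspect labels present (e.g. "BP", "MF", "CC").
#' @return a [gene_set_collection()] of term memberships for that aspect.
#' @export
go_gene_sets <- function(annotations, aspect) {
  stopifnot(all(c("gene", "aspect", "term") %in% names(annotations)))
  ann <- annotations[annotations$aspect == aspect, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop(sprintf("no annotations for aspect '%s' (available: %s)", aspect,
                 paste(unique(annotations$aspect), collapse = ", ")),
         call. = FALSE)
  }
  gene_set_collection(split(toupper(ann$gene), ann$term))
}

#' Permutation test of the perfect-homogeneity count
#'
#' Counts the diseases with perfect homogeneity (PH = 1) and compares the
#' count against a null in which each scorable disease's genes are replaced
#' by a uniform random sample of the same size drawn from the universe of
#' annotated genes (the genes appearing in the set collection). The
#' z-score is (real count - null mean) / null sd, the p-value its upper
#' normal tail, and the fold change real count / null mean count. Diseases
#' with no annotated gene are excluded from the count in both the real and
#' the null runs.
#'
#' @param dgm a [disease_gene_map()].
#' @param sets a [gene_set_collection()].
#' @param n_trials number of null trials (>= 100; default 10,000).
#' @param seed integer seed recorded in the report.
#' @return a `null_summary` (statistic `"perfect_homogeneity_count"`) with
#'   an extra `n_scored` field.
#' @export
perfect_homogeneity_test <- function(dgm, sets, n_trials = 10000, seed = 1L) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  if (n_trials < 100) stop("n_trials must be >= 100", call. = FALSE)
  idx <- gene_set_index(sets)
  universe <- names(idx)
  scored <- lapply(dgm$genes, function(g) ph_core(g, idx))
  defined <- vapply(scored, `[[`, logical(1), "defined")
  # each null trial redraws the disease's ANNOTATED gene count n_i from the
  # annotated universe: PH is a statistic of the n_i annotated genes, so the
  # matched null must hold n_i fixed, not the raw gene-set size
  sizes <- vapply(scored[defined], function(s) s$n_i, integer(1))
  sizes <- pmin(sizes, length(universe))
  real <- sum(vapply(scored[defined], `[[`, numeric(1), "ph") == 1)
  null_values <- withr::with_seed(seed, {
    vapply(seq_len(n_trials), function(t) {
      sum(vapply(sizes, function(sz) {
        ph_core(sample(universe, sz), idx)$ph == 1
      }, logical(1)))
    }, numeric(1))
  })
  out <- null_summary("perfect_homogeneity_count", real, null_values,
                      n_trials, seed)
  out$n_scored <- sum(defined)
  out
}

#' Mean disease degree per homogeneity bin
#'
#' @param d projected diseasome graph.
#' @param scores score data.frame from [homogeneity_profile()] (`$scores`).
#' @param n_bins number of homogeneity bins over (0, 1].
#' @return `data.frame` with `bin_low`, `bin_high`, `center`,
#'   `mean_degree`, `n_diseases` for non-empty bins.
#' @export
degree_vs_homogeneity <- function(d, scores, n_bins = 10) {
  deg <- stats::setNames(igraph::degree(d), igraph::V(d)$name)
  common <- intersect(scores$disease_id, names(deg))
  skipped <- setdiff(scores$disease_id, names(deg))
  if (length(skipped) > 0) {
    message(sprintf("degree_vs_homogeneity: %d scored disease(s) not in graph",
                    length(skipped)))
  }
  s <- scores[scores$disease_id %in% common, , drop = FALSE]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(s$ph, breaks, include.lowest = FALSE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- which(bin == b)
    data.frame(bin_low = breaks[b], bin_high = breaks[b + 1],
               center = (breaks[b] + breaks[b + 1]) / 2,
               mean_degree = mean(deg[s$disease_id[sel]]),
               n_diseases = length(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Mean endpoint homogeneity per shared-gene count
#'
#' For each observed link weight (shared-gene count), the mean over links
#' of the average of the two endpoint homogeneity scores. Links with an
#' unscored endpoint are skipped with a log message.
#'
#' @param d projected diseasome graph with integer edge `weight`.
#' @param scores score data.frame from [homogeneity_profile()] (`$scores`).
#' @return `data.frame` with `shared_genes`, `mean_ph`, `n_links`.
#' @export
shared_genes_vs_mean_ph <- function(d, scores) {
  el <- igraph::as_data_frame(d, what = "edges")
  ph <- stats::setNames(scores$ph, scores$disease_id)
  ok <- el$from %in% names(ph) & el$to %in% names(ph)
  if (any(!ok)) {
    message(sprintf("shared_genes_vs_mean_ph: %d link(s) with unscored endpoint skipped",
                    sum(!ok)))
  }
  el <- el[ok, , drop = FALSE]
  if (nrow(el) == 0L) {
    return(data.frame(shared_genes = integer(0), mean_ph = numeric(0),
                      n_links = integer(0)))
  }
  pair_ph <- (ph[el$from] + ph[el$to]) / 2
  agg <- stats::aggregate(pair_ph, by = list(shared_genes = el$weight), FUN = mean)
  cnt <- table(el$weight)
  out <- data.frame(shared_genes = as.integer(agg$shared_genes),
                    mean_ph = agg$x,
                    n_links = as.integer(cnt[as.character(agg$shared_genes)]))
  out[order(out$shared_genes), , drop = FALSE]
}
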