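#' Node centralities of a diseasome
#'
#' Degree, betweenness and closeness for every node, computed on the
#' unweighted topology. Betweenness is the raw count of shortest paths
#' through a node (each unordered pair counted once). On disconnected
#' graphs both are computed per connected component; closeness uses the
#' within-component convention scaled by component size,
#' \eqn{C(v) = \frac{n_c - 1}{\sum_{u} d(v, u)} \cdot \frac{n_c - 1}{n - 1}},
#' so values stay in \[0, 1\] and isolated nodes score 0.
#'
#' @param d an igraph graph (e.g. from [project()]).
#' @return `data.frame` with columns `disease`, `degree`, `betweenness`,
#'   `closeness`, one row per node (isolated nodes included).
#' @export
centralities <- function(d) {
  n <- igraph::vcount(d)
  if (n == 0L) stop("centralities: empty graph", call. = FALSE)
  deg <- igraph::degree(d)
  btw <- igraph::betweenness(d, weights = NA)
  comp <- igraph::components(d)
  clo <- numeric(n)
  dist <- igraph::distances(d, weights = NA)
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    nc <- length(idx)
    if (nc == 1L) {
      clo[idx] <- 0
      next
    }
    within <- rowSums(dist[idx, idx, drop = FALSE])
    scale <- if (n > 1L) (nc - 1) / (n - 1) else 1
    clo[idx] <- (nc - 1) / within * scale
  }
  data.frame(disease = igraph::V(d)$name %||% as.character(seq_len(n)),
             degree = as.integer(deg),
             betweenness = unname(btw),
             closeness = clo,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logarithmically binned distribution
#'
#' Bins positive values into geometric (equal log-width) bins with
#' `bins_per_decade` bins per factor of ten, starting at the minimum value.
#' Each value is counted exactly once. Both the normalized frequency
#' (summing to 1) and the width-normalized density (frequency / bin width,
#' the standard presentation for heavy-tailed degree data) are reported.
#'
#' @param values non-empty vector of positive numbers.
#' @param bins_per_decade integer >= 1.
#' @param drop_empty drop bins with zero counts (default TRUE).
#' @return `data.frame` with columns `bin_low`, `bin_high`, `center`
#'   (geometric mean of the bounds), `count`, `frequency`, `density`.
#' @export
log_binned_distribution <- function(values, bins_per_decade = 5, drop_empty = TRUE) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  if (bins_per_decade < 1) stop("bins_per_decade must be >= 1", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  r <- 10^(1 / bins_per_decade)
  n_bins <- if (hi == lo) 1L else floor(log10(hi / lo) * bins_per_decade) + 1L
  edges <- lo * r^(0:n_bins)
  # guard against floating point placing max outside the last bin
  while (edges[length(edges)] <= hi) edges <- c(edges, edges[length(edges)] * r)
  bin <- findInterval(values, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  out <- data.frame(bin_low = edges[-length(edges)],
                    bin_high = edges[-1],
                    center = sqrt(edges[-length(edges)] * edges[-1]),
                    count = counts)
  out$frequency <- out$count / sum(out$count)
  out$density <- out$frequency / (out$bin_high - out$bin_low)
  if (drop_empty) out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diseasome summary statistics
#'
#' Convenience wrapper collecting node/edge counts, centralities, and the
#' log-binned degree and per-disease gene-count distributions.
#'
#' @param d projected diseasome graph with a `gene_count` vertex attribute.
#' @param bins_per_decade bins per decade for the log-binned distributions.
#' @return list with `n_diseases`, `n_links`, `centralities`,
#'   `degree_distribution`, `gene_size_distribution`.
#' @export
diseasome_stats <- function(d, bins_per_decade = 5) {
  cen <- centralities(d)
  deg <- cen$degree[cen$degree > 0]
  gs <- igraph::V(d)$gene_count
  list(
    n_diseases = igraph::vcount(d),
    n_links = igraph::ecount(d),
    centralities = cen,
    degree_distribution = if (length(deg) > 0)
      log_binned_distribution(deg, bins_per_decade) else NULL,
    gene_size_distribution = if (!is.null(gs) && length(gs[gs > 0]) > 0)
      log_binned_distribution(gs[gs > 0], bins_per_decade) else NULL
  )
}
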