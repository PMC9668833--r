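#' Hypergeometric connectivity probability mass
#'
#' Probability that, in a network of `N` proteins containing `s0` module
#' ("seed") proteins, a protein with `k` links has exactly `k_s` links to
#' the module:
#' \deqn{p(k, k_s) = \frac{\binom{s_0}{k_s} \binom{N - s_0}{k - k_s}}{\binom{N}{k}}}
#' Evaluated in log space for numerical stability.
#'
#' @param k total degree of the protein.
#' @param k_s links into the module, `0 <= k_s <= min(k, s0)`.
#' @param N number of proteins in the network.
#' @param s0 current module size.
#' @return probability in \[0, 1\].
#' @export
hypergeom_pmf <- function(k, k_s, N, s0) {
  check_hyper_args(k, k_s, N, s0)
  exp(lchoose(s0, k_s) + lchoose(N - s0, k - k_s) - lchoose(N, k))
}

check_hyper_args <- function(k, k_s, N, s0) {
  ok <- k >= 0 & N >= 1 & s0 >= 0 & s0 <= N & k <= N &
    k_s >= 0 & k_s <= k & k_s <= s0 & (k - k_s) <= (N - s0)
  if (!all(ok)) {
    stop(sprintf("invalid hypergeometric arguments: k=%s, k_s=%s, N=%s, s0=%s",
                 k[!ok][1], k_s[!ok][1], N[!ok][1], s0[!ok][1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Hypergeometric connectivity p-value
#'
#' Upper-tail cumulative probability that a protein of degree `k` has at
#' least `k_s` links to the module:
#' \eqn{p = \sum_{k_i = k_s}^{\min(k, s_0)} p(k, k_i)}, summed in log
#' space. The upper limit is capped at `min(k, s0)` since the mass is zero
#' beyond the support.
#'
#' @inheritParams hypergeom_pmf
#' @return p-value in (0, 1\].
#' @export
connectivity_pvalue <- function(k, k_s, N, s0) {
  check_hyper_args(k, k_s, N, s0)
  hi <- min(k, s0)
  ki <- k_s:hi
  lg <- lchoose(s0, ki) + lchoose(N - s0, k - ki) - lchoose(N, k)
  m <- max(lg)
  p <- exp(m + log(sum(exp(lg - m))))
  min(p, 1)
}

#' DIAMOnD iterative candidate-gene ranking
#'
#' Starting from a seed-gene module on an interactome, each iteration
#' scores every non-module gene with at least one link into the current
#' module by its connectivity p-value ([connectivity_pvalue()]), with `s0`
#' the current module size, and moves the most significant gene into the
#' module. Newly added genes count as module members for subsequent rounds;
#' with `fixed_s0 = TRUE` (sensitivity variant) `s0` stays frozen at the
#' original seed count and the p-value scores links to the original seeds
#' only, while eligibility still follows the growing module. Ties in
#' p-value (compared after rounding to 12 significant digits, so
#' mathematically equal tails reached through different summation orders
#' compare equal) are broken by higher `k_s`, then lexicographic gene id,
#' so rankings are fully deterministic.
#'
#' @param g an igraph graph (undirected, simple) or an edge-list
#'   `data.frame` (`node_a`, `node_b`).
#' @param seeds character vector of seed gene ids; at least one must be
#'   present in the graph (absent seeds are dropped with a warning).
#' @param n_iterations maximum number of genes to rank (default 1000).
#' @param fixed_s0 logical; see above.
#' @return object of class `diamond_ranking`: `data.frame` with columns
#'   `rank`, `gene`, `k`, `k_s`, `p_value`, with the seed set and graph
#'   size as attributes.
#' @export
diamond_rank <- function(g, seeds, n_iterations = 1000, fixed_s0 = FALSE) {
  if (is.data.frame(g)) {
    g <- igraph::graph_from_data_frame(g[, 1:2], directed = FALSE)
  }
  stopifnot(igraph::is_igraph(g))
  g <- igraph::simplify(g)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  nodes <- igraph::V(g)$name
  seeds <- unique(seeds)
  absent <- setdiff(seeds, nodes)
  if (length(absent) == length(seeds)) {
    stop("no seed gene is present in the interactome", call. = FALSE)
  }
  if (length(absent) > 0) {
    warning(sprintf("%d seed gene(s) absent from the interactome dropped",
                    length(absent)), call. = FALSE)
    seeds <- setdiff(seeds, absent)
  }
  N <- length(nodes)
  adj <- igraph::as_adj_list(g)
  names(adj) <- nodes
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  deg <- stats::setNames(as.integer(igraph::degree(g)), nodes)

  in_module <- stats::setNames(rep(FALSE, N), nodes)
  in_module[seeds] <- TRUE
  # k_s bookkeeping: links from each non-module node into the module
  # (eligibility); under fixed_s0 the p-value instead scores links to the
  # ORIGINAL seed set, which the frozen s0 refers to
  ks <- stats::setNames(integer(N), nodes)
  for (s in seeds) {
    nb <- adj[[s]]
    ks[nb] <- ks[nb] + 1L
  }
  ks_seed <- ks
  s0 <- length(seeds)
  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    cand <- names(ks)[ks > 0L & !in_module]
    if (length(cand) == 0L) {
      message(sprintf("diamond_rank: candidates exhausted after %d iteration(s)",
                      it - 1L))
      rows <- rows[seq_len(it - 1L)]
      break
    }
    kc <- deg[cand]
    ksc <- if (fixed_s0) ks_seed[cand] else ks[cand]
    key <- paste(kc, ksc)
    pv_unique <- vapply(unique(key), function(kk) {
      v <- as.integer(strsplit(kk, " ", fixed = TRUE)[[1]])
      connectivity_pvalue(v[1], v[2], N, s0)
    }, numeric(1))
    pv <- pv_unique[key]
    # ordering on p rounded to 12 significant digits: mathematically tied
    # p-values reached through different summation orders compare equal
    ord <- order(signif(pv, 12), -ksc, cand)[1]
    best <- cand[ord]
    rows[[it]] <- data.frame(rank = it, gene = best, k = unname(kc[ord]),
                             k_s = unname(ksc[ord]),
                             p_value = unname(pv[ord]))
    in_module[best] <- TRUE
    nb <- adj[[best]]
    ks[nb] <- ks[nb] + 1L
    if (!fixed_s0) s0 <- s0 + 1L
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(rank = integer(0), gene = character(0), k = integer(0),
                      k_s = integer(0), p_value = numeric(0))
  }
  rownames(out) <- NULL
  structure(out, seeds = seeds, N = N, fixed_s0 = fixed_s0,
            class = c("diamond_ranking", "data.frame"))
}

#' Write a DIAMOnD ranking as TSV
#'
#' @param ranking a `diamond_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diamond_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking)[c("rank", "gene", "k", "k_s",
                                              "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
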