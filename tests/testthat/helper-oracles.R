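# Fixture builders and independent brute-force oracles used across tests.

# disease-gene table from a named list of gene vectors
make_table <- function(map, category = "cardiovascular") {
  cats <- rep_len(category, length(map))
  data.frame(disease_id = rep(names(map), lengths(map)),
             category = rep(cats, lengths(map)),
             gene = toupper(unlist(map, use.names = FALSE)))
}

make_map <- function(map, category = "cardiovascular") {
  disease_gene_map(suppressMessages(
    validate_disease_gene_table(make_table(map, category))))
}

# brute-force bipartite projection: all pairwise set intersections
brute_project <- function(genes_list) {
  ids <- names(genes_list)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        w <- length(intersect(genes_list[[i]], genes_list[[j]]))
        if (w > 0) {
          a <- sort(c(ids[i], ids[j]))
          rows[[length(rows) + 1]] <-
            data.frame(from = a[1], to = a[2], weight = w)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

# canonical sorted edge data frame of a projected diseasome
diseasome_edges <- function(d) {
  el <- igraph::as_data_frame(d, what = "edges")
  if (nrow(el) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      weight = integer(0)))
  }
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  out <- data.frame(from = a, to = b, weight = el$weight)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent DIAMOnD re-implementation: recomputes the hypergeometric tail
# for every connected candidate each round with stats::phyper
brute_diamond <- function(g, seeds, n_iter, fixed_s0 = FALSE) {
  nodes <- igraph::V(g)$name
  N <- length(nodes)
  nbrs <- lapply(igraph::as_adj_list(g), function(v) nodes[as.integer(v)])
  names(nbrs) <- nodes
  seeds <- intersect(seeds, nodes)
  module <- seeds
  s0 <- length(module)
  picked <- character(0)
  for (it in seq_len(n_iter)) {
    cand <- setdiff(nodes, module)
    ks_mod <- vapply(cand, function(v) length(intersect(nbrs[[v]], module)),
                     integer(1))
    cand <- cand[ks_mod > 0]
    if (length(cand) == 0) break
    ks <- if (fixed_s0) {
      vapply(cand, function(v) length(intersect(nbrs[[v]], seeds)),
             integer(1))
    } else {
      ks_mod[ks_mod > 0]
    }
    k <- vapply(cand, function(v) length(nbrs[[v]]), integer(1))
    p <- stats::phyper(ks - 1, s0, N - s0, k, lower.tail = FALSE)
    best <- cand[order(signif(p, 12), -ks, cand)[1]]
    picked <- c(picked, best)
    module <- c(module, best)
    if (!fixed_s0) s0 <- s0 + 1
  }
  picked
}

# Benjamini-Hochberg step-up, written directly from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# one-sided Fisher p as an explicit hypergeometric tail sum over the table
brute_fisher_greater <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  m1 <- a + b  # row 1 total (e.g. window size)
  k1 <- a + c_ # column 1 total (e.g. universe size)
  i <- a:min(m1, k1)
  sum(exp(lchoose(m1, i) + lchoose(n - m1, k1 - i) - lchoose(n, k1)))
}
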