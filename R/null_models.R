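#' Shuffle the genes of every disease
#'
#' The randomization behind the permutation null: each disease keeps its
#' category and its gene-set size, but its genes are redrawn uniformly
#' without replacement (within the disease) from the pooled set of all
#' genes in the map; a gene may appear in several diseases. With
#' `preserve_gene_degree = TRUE` the gene column of the long
#' (disease, gene) table is permuted instead, preserving every gene's
#' disease-multiplicity exactly (collisions within a disease are collapsed,
#' which can shrink a set slightly; logged).
#'
#' @param dgm a [disease_gene_map()].
#' @param seed integer seed; the shuffle is deterministic given the seed.
#' @param preserve_gene_degree logical, see above.
#' @return a shuffled `disease_gene_map`.
#' @export
shuffle_disease_genes <- function(dgm, seed, preserve_gene_degree = FALSE) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  pool <- unique(unlist(dgm$genes, use.names = FALSE))
  sizes <- lengths(dgm$genes)
  if (any(sizes > length(pool))) {
    stop("a disease has more genes than the pooled gene universe", call. = FALSE)
  }
  genes <- withr::with_seed(seed, {
    if (preserve_gene_degree) {
      long <- unlist(dgm$genes, use.names = FALSE)
      disease <- rep(names(dgm$genes), sizes)
      shuffled <- sample(long)
      out <- lapply(split(shuffled, disease), unique)
      lost <- sum(sizes) - sum(lengths(out))
      if (lost > 0) {
        message(sprintf(
          "degree-preserving shuffle: %d collision(s) collapsed", lost))
      }
      out[names(dgm$genes)]
    } else {
      lapply(dgm$genes, function(g) sample(pool, length(g)))
    }
  })
  structure(list(genes = genes, category = dgm$category),
            class = "disease_gene_map")
}

# Normal-theory summary of a real statistic against permutation null draws.
null_summary <- function(statistic, real, null_values, n_trials, seed) {
  mu <- mean(null_values)
  sigma <- stats::sd(null_values)
  degenerate <- !is.finite(sigma) || sigma == 0
  z <- if (degenerate) NA_real_ else (real - mu) / sigma
  structure(list(
    statistic = statistic,
    real = real,
    null_mean = mu,
    null_sd = sigma,
    z_score = z,
    p_value = if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
    p_empirical = (1 + sum(null_values >= real)) / (n_trials + 1),
    fold_change = if (mu > 0) real / mu else NA_real_,
    n_trials = n_trials,
    seed = seed,
    degenerate = degenerate
  ), class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "null_summary [%s]: real = %.4g, null = %.4g +/- %.4g (%d trials)\n",
    x$statistic, x$real, x$null_mean, x$null_sd, x$n_trials))
  if (x$degenerate) {
    cat("  degenerate null (sd = 0): no z-score\n")
  } else {
    cat(sprintf("  z = %.4g, p(normal, upper) = %.4g, fold change = %.4g\n",
                x$z_score, x$p_value, x$fold_change))
  }
  invisible(x)
}

#' Permutation significance of anchor-restricted diseasome link count
#'
#' The observed statistic is the number of links of the anchor-restricted,
#' projected diseasome. The null distribution is obtained by shuffling
#' every disease's genes ([shuffle_disease_genes()]), re-restricting to the
#' anchor and re-projecting, `n_trials` times (default 10,000). Normal
#' z-score and one-sided upper-tail p-value are reported alongside an
#' empirical permutation p-value.
#'
#' @param dgm a [disease_gene_map()].
#' @param anchor_genes anchor gene set (e.g. cardiomyopathy genes).
#' @param n_trials number of random trials (>= 100).
#' @param seed integer seed recorded in the report.
#' @param preserve_gene_degree passed to [shuffle_disease_genes()].
#' @return a `null_summary` object.
#' @export
null_link_significance <- function(dgm, anchor_genes, n_trials = 10000,
                                   seed = 1L, preserve_gene_degree = FALSE) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  if (n_trials < 100) stop("n_trials must be >= 100", call. = FALSE)
  anchor_genes <- toupper(anchor_genes)
  real <- anchor_link_count(dgm$genes, anchor_genes)$links
  null_values <- withr::with_seed(seed, {
    trial_seeds <- sample.int(.Machine$integer.max, n_trials)
    vapply(trial_seeds, function(s) {
      sh <- shuffle_disease_genes(dgm, s, preserve_gene_degree)
      anchor_link_count(sh$genes, anchor_genes)$links
    }, numeric(1))
  })
  null_summary("anchor_restricted_link_count", real, null_values,
               n_trials, seed)
}

#' Intra-category link counts of a diseasome
#'
#' Number of links whose two disease endpoints share the same category.
#'
#' @param d projected diseasome graph with a `category` vertex attribute.
#' @return named integer vector, one entry per category present.
#' @export
intra_category_links <- function(d) {
  cats <- sort(unique(igraph::V(d)$category))
  el <- igraph::as_data_frame(d, what = "edges")
  cat_of <- stats::setNames(igraph::V(d)$category, igraph::V(d)$name)
  counts <- stats::setNames(integer(length(cats)), cats)
  if (nrow(el) > 0) {
    same <- cat_of[el$from] == cat_of[el$to]
    tab <- table(factor(cat_of[el$from][same], levels = cats))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Permutation significance of intra-category link counts
#'
#' As [null_link_significance()], but the statistic is the per-category
#' count of links joining two diseases of the same category.
#'
#' @inheritParams null_link_significance
#' @return named list of `null_summary` objects, one per category present
#'   among anchor-restricted diseases.
#' @export
intra_category_significance <- function(dgm, anchor_genes, n_trials = 10000,
                                        seed = 1L,
                                        preserve_gene_degree = FALSE) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  if (n_trials < 100) stop("n_trials must be >= 100", call. = FALSE)
  anchor_genes <- toupper(anchor_genes)
  real <- anchor_link_count(dgm$genes, anchor_genes, per_category = dgm$category)
  cats <- names(real$intra)
  null_mat <- withr::with_seed(seed, {
    trial_seeds <- sample.int(.Machine$integer.max, n_trials)
    vapply(trial_seeds, function(s) {
      sh <- shuffle_disease_genes(dgm, s, preserve_gene_degree)
      cnt <- anchor_link_count(sh$genes, anchor_genes,
                               per_category = dgm$category)$intra
      out <- stats::setNames(numeric(length(cats)), cats)
      out[names(cnt)] <- cnt
      out
    }, numeric(length(cats)))
  })
  if (length(cats) == 1L) null_mat <- matrix(null_mat, nrow = 1,
                                             dimnames = list(cats, NULL))
  out <- lapply(cats, function(cc) {
    null_summary(paste0("intra_category_links[", cc, "]"),
                 real$intra[[cc]], null_mat[cc, ], n_trials, seed)
  })
  stats::setNames(out, cats)
}

#' Flatten null summaries to a data.frame
#'
#' @param x a `null_summary` or list of them.
#' @return `data.frame` with one row per summary.
#' @export
null_summary_table <- function(x) {
  if (inherits(x, "null_summary")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    data.frame(statistic = s$statistic, real = s$real, null_mean = s$null_mean,
               null_sd = s$null_sd, z_score = s$z_score, p_value = s$p_value,
               p_empirical = s$p_empirical, fold_change = s$fold_change,
               n_trials = s$n_trials, seed = s$seed, degenerate = s$degenerate)
  }))
}
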