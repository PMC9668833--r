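#' Disease category vocabulary
#'
#' The closed vocabulary of disease categories used throughout the package:
#' twelve organ-system categories plus `"multiple"` for diseases whose
#' category votes are tied between two or more dominant categories.
#'
#' @param include_multiple logical; include the `"multiple"` label.
#' @return character vector of category names.
#' @export
#' @examples
#' disease_categories()
disease_categories <- function(include_multiple = TRUE) {
  cats <- c(
    "cardiovascular", "musculoskeletal", "congenital", "neoplasms",
    "metabolic", "nervous", "respiratory", "digestive", "urogenital",
    "immunological", "endocrine", "hematological"
  )
  if (include_multiple) c(cats, "multiple") else cats
}

#' Read a disease-gene association table
#'
#' Reads a tab-separated table with required header columns `disease_id`,
#' `category` and `gene`. Gene symbols are trimmed and uppercased at the
#' boundary (HGNC-style normalization; synonym resolution is out of scope).
#' Duplicate `(disease_id, gene)` rows are collapsed, keeping the first
#' occurrence; a load report (rows read / rows dropped) is emitted as a
#' message.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with columns `disease_id`, `category`, `gene`.
#' @export
read_disease_gene_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  validate_disease_gene_table(df, context = path)
}

#' Validate a disease-gene table held in memory
#'
#' Applies the same checks and normalization as [read_disease_gene_table()].
#'
#' @param df data.frame with columns `disease_id`, `category`, `gene`.
#' @param context label used in error messages (defaults to "table").
#' @return validated, deduplicated `data.frame`.
#' @export
validate_disease_gene_table <- function(df, context = "table") {
  required <- c("disease_id", "category", "gene")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s): %s",
                 context, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  n_read <- nrow(df)
  if (n_read == 0L) {
    warning(sprintf("%s contains a header but no data rows", context),
            call. = FALSE)
    return(df)
  }
  df$disease_id <- trimws(df$disease_id)
  df$category <- trimws(df$category)
  df$gene <- toupper(trimws(df$gene))
  bad_gene <- which(!nzchar(df$gene) | !nzchar(df$disease_id))
  if (length(bad_gene) > 0) {
    stop(sprintf("validation error in %s: empty disease_id/gene in row(s) %s",
                 context, paste(utils::head(bad_gene, 10), collapse = ", ")),
         call. = FALSE)
  }
  bad_cat <- which(!(df$category %in% disease_categories()))
  if (length(bad_cat) > 0) {
    stop(sprintf(
      "validation error in %s: unknown category in row(s) %s (categories: %s)",
      context, paste(utils::head(bad_cat, 10), collapse = ", "),
      paste(unique(df$category[bad_cat]), collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(df[c("disease_id", "gene")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("%s: %d rows read, %d duplicate (disease, gene) rows dropped",
                  context, n_read, sum(dup)))
  df
}

#' Write a disease-gene table as TSV
#'
#' @param df validated disease-gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_gene_table <- function(df, path) {
  utils::write.table(df[c("disease_id", "category", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A gene-set collection is a named list of character vectors (member gene
#' symbols, uppercased, deduplicated) with a `descriptions` attribute.
#' Carrier for pathway collections (MSigDB-style) and per-aspect GO term
#' memberships.
#'
#' @param members named list of character vectors; names are set ids.
#' @param descriptions optional character vector parallel to `members`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(members, descriptions = NULL) {
  if (is.null(names(members)) || anyDuplicated(names(members))) {
    stop("set ids must be unique and non-empty", call. = FALSE)
  }
  members <- lapply(members, function(g) unique(toupper(trimws(g))))
  sizes <- lengths(members)
  if (any(sizes == 0L)) {
    stop(sprintf("empty gene set(s): %s",
                 paste(names(members)[sizes == 0L], collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(members))
  structure(members, descriptions = stats::setNames(descriptions, names(members)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard header-less GMT dialect: one set per line,
#' `set_id TAB description TAB gene1 TAB gene2 ...`. Duplicate member
#' symbols within a line are collapsed; duplicate set ids across lines are
#' an error.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop(sprintf("format error in %s: empty GMT file", path), call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    stop(sprintf("format error in %s: line %d has fewer than 3 fields",
                 path, short[1]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("format error in %s: duplicate set id '%s'",
                 path, ids[duplicated(ids)][1]), call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  names(members) <- ids
  gene_set_collection(members, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Header-less tab-separated node pairs with an optional third numeric
#' weight column. Edges are undirected: `(a, b)` and `(b, a)` collapse to a
#' single edge (first weight kept). Self-loops are dropped and their count
#' logged.
#'
#' @param path path to a TSV edge list.
#' @return `data.frame` with columns `node_a`, `node_b` and (if present)
#'   `weight`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(node_a = character(0), node_b = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("format error in %s: line %d has fewer than 2 fields",
                 path, which(nf < 2L)[1]), call. = FALSE)
  }
  df <- data.frame(node_a = vapply(fields, `[[`, character(1), 1L),
                   node_b = vapply(fields, `[[`, character(1), 2L))
  if (any(nf >= 3L)) {
    w_chr <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1",
                    character(1))
    w <- suppressWarnings(as.numeric(w_chr))
    if (anyNA(w)) {
      stop(sprintf("format error in %s: non-numeric weight on line %d",
                   path, which(is.na(w))[1]), call. = FALSE)
    }
    df$weight <- w
  }
  normalize_edge_list(df, context = path)
}

#' Normalize an edge list in memory
#'
#' Drops self-loops (logged), orients each pair canonically and removes
#' duplicate undirected edges.
#'
#' @param df data.frame with columns `node_a`, `node_b`, optional `weight`.
#' @param context label for log messages.
#' @return normalized `data.frame`.
#' @export
normalize_edge_list <- function(df, context = "edge list") {
  loops <- df$node_a == df$node_b
  if (any(loops)) {
    message(sprintf("%s: dropped %d self-loop(s)", context, sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  if (nrow(df) > 0) {
    a <- pmin(df$node_a, df$node_b)
    b <- pmax(df$node_a, df$node_b)
    df$node_a <- a
    df$node_b <- b
    dup <- duplicated(df[c("node_a", "node_b")])
    df <- df[!dup, , drop = FALSE]
    df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write an edge list as TSV
#'
#' @param df edge-list data.frame (`node_a`, `node_b`, optional `weight`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a mouse-to-human ortholog table
#'
#' TSV with header columns `mouse_gene` and `human_gene`; human symbols are
#' uppercased. Many-to-one mappings are allowed and retained.
#'
#' @param path path to TSV file.
#' @return `data.frame` with columns `mouse_gene`, `human_gene`.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  missing_cols <- setdiff(c("mouse_gene", "human_gene"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$human_gene <- toupper(trimws(df$human_gene))
  df$mouse_gene <- trimws(df$mouse_gene)
  df <- df[!duplicated(df[c("mouse_gene", "human_gene")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a long-format gene expression table
#'
#' TSV with header columns `gene`, `tissue`, `ptpm` (protein-coding
#' transcripts per million, non-negative).
#'
#' @param path path to TSV file.
#' @return `data.frame` with columns `gene`, `tissue`, `ptpm`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "")
  missing_cols <- setdiff(c("gene", "tissue", "ptpm"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error in %s: missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$gene <- toupper(trimws(df$gene))
  df$ptpm <- as.numeric(df$ptpm)
  if (anyNA(df$ptpm) || any(df$ptpm < 0)) {
    stop(sprintf("validation error in %s: ptpm must be numeric and >= 0", path),
         call. = FALSE)
  }
  df
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path path to a text file.
#' @return character vector of uppercased unique symbols.
#' @export
read_gene_list <- function(path) {
  g <- readLines(path, warn = FALSE)
  g <- toupper(trimws(g))
  unique(g[nzchar(g)])
}
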