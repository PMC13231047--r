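# Readers and writers for the plain-text interchange formats the pipeline
# consumes and emits. All tables go through readr; graphs through igraph.

#' Read / write a genes x samples expression matrix as TSV
#'
#' First column holds gene ids, remaining columns one sample each.
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  check_expr(m, path)
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @export
write_expression <- function(expr, path) {
  check_expr(expr, "expr")
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (sample, group, optional survival)
#'
#' @param path File path.
#' @return A tibble with at least `sample` and `group` columns.
#' @export
read_phenotype <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_phenotype
#' @param pheno Tibble with a `sample` column.
#' @export
write_phenotype <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Each GMT line is tab-separated: set name, description, then one or more
#' member genes.
#'
#' @param path File path.
#' @return A tibble with columns `set`, `description`, `genes` (list of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)", bad[1], path))
  }
  tibble(
    set = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) p[-(1:2)])
  )
}

#' @rdname read_gmt
#' @param collection Tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(all(c("set", "description", "genes") %in% names(collection)))
  if (any(lengths(collection$genes) < 1L)) {
    abort("every GMT set needs at least one gene")
  }
  lines <- mapply(
    function(s, d, g) paste(c(s, d, g), collapse = "\t"),
    collection$set, collection$description, collection$genes
  )
  writeLines(lines, path)
  invisible(path)
}

# Convert a GMT tibble to a named list of gene vectors.
gmt_as_list <- function(collection) {
  setNames(collection$genes, collection$set)
}

#' Read / write a scored edge table (combined_score on the 0-1000 scale)
#'
#' @param path File path.
#' @return A tibble with columns `node1`, `node2`, `combined_score`.
#' @export
read_edge_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("node1", "node2", "combined_score")
  if (!all(need %in% names(df))) {
    abort(sprintf("edge table %s must have columns %s", path, paste(need, collapse = ", ")))
  }
  bad <- which(is.na(df$node1) | is.na(df$node2) | is.na(df$combined_score))
  if (length(bad)) {
    abort(sprintf("malformed edge table line %d in %s", bad[1] + 1L, path))
  }
  df[need]
}

#' @rdname read_edge_table
#' @param edges Tibble with columns `node1`, `node2`, `combined_score`.
#' @export
write_edge_table <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read / write SIF (simple interaction format)
#'
#' Lines are `source <tab> interaction <tab> target`.
#'
#' @param path File path.
#' @param interaction Relationship label used for all edges on write.
#' @return A tibble with columns `node1`, `interaction`, `node2`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(node1 = character(), interaction = character(), node2 = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) {
    abort(sprintf("malformed SIF line %d in %s", bad[1], path))
  }
  tibble(
    node1 = vapply(parts, `[[`, "", 1L),
    interaction = vapply(parts, `[[`, "", 2L),
    node2 = vapply(parts, `[[`, "", 3L)
  )
}

#' @rdname read_sif
#' @param edges Tibble with columns `node1`, `node2` (and optionally
#'   `interaction`).
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  if (nrow(edges) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rel <- if ("interaction" %in% names(edges)) edges$interaction else interaction
  writeLines(paste(edges$node1, rel, edges$node2, sep = "\t"), path)
  invisible(path)
}

#' Write a gene set as one-gene-per-line text
#'
#' @param genes Character vector.
#' @param path File path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sorted_unique(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
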