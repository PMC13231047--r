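#' Filter the disease-B association tables
#'
#' Keeps genes passing the relevance filter (`relevance >= relevance_min`,
#' inclusive) in the relevance source AND the literature filter
#' (`pmid_count >= pmid_min`, i.e. strictly more than zero PMIDs at the
#' default) in the curation source — the intersection of the two filtered
#' lists, deduplicated and sorted.
#'
#' @param tables Association tibble with columns `gene_id`, `source`
#'   (`relevance_source` / `curation_source`), `relevance`, `pmid_count`.
#' @param relevance_min Minimum relevance score (default 10, inclusive).
#' @param pmid_min Minimum PMID count (default 1).
#' @return Sorted character vector of gene ids.
#' @export
filter_disease_b <- function(tables, relevance_min = 10, pmid_min = 1) {
  need <- c("gene_id", "source", "relevance", "pmid_count")
  if (!all(need %in% names(tables))) {
    abort(sprintf("association table needs columns %s", paste(need, collapse = ", ")))
  }
  srcs <- unique(tables$source)
  if (!all(c("relevance_source", "curation_source") %in% srcs)) {
    abort("both association sources must be present")
  }
  rel_pass <- tables$gene_id[
    tables$source == "relevance_source" &
      !is.na(tables$relevance) & tables$relevance >= relevance_min
  ]
  cur_pass <- tables$gene_id[
    tables$source == "curation_source" &
      !is.na(tables$pmid_count) & tables$pmid_count >= pmid_min
  ]
  sorted_unique(intersect(rel_pass, cur_pass))
}

#' Derive the disease-A gene set by three-step intersection
#'
#' Step 1: direction-consistent DEG intersection of the two primary
#' datasets (provided as `consistent_degs`). Step 2: step 1 restricted to
#' DEGs from the second, unmoderated DE configuration (direction
#' consistency applied the same way). Step 3: the intersection of the two
#' datasets' strongest-module gene sets. The result is the deduplicated
#' intersection of steps 2 and 3.
#'
#' @param consistent_degs List with `up`/`down` from [intersect_consistent()]
#'   over the moderated fits.
#' @param degs_config2 Same structure from the second (unmoderated) DE
#'   configuration.
#' @param module_genes_1,module_genes_2 Strongest-module gene vectors for
#'   the two datasets.
#' @return A list of class `disease_a_set` with `genes` (the final set),
#'   `steps` (the intermediate sets), and `provenance` (per-gene tibble of
#'   which step removed it).
#' @export
derive_disease_a <- function(consistent_degs, degs_config2,
                             module_genes_1, module_genes_2) {
  step1 <- sorted_unique(c(consistent_degs$up, consistent_degs$down))
  step2_dir <- intersect_consistent(consistent_degs, degs_config2)
  step2 <- sorted_unique(c(step2_dir$up, step2_dir$down))
  step3 <- sorted_unique(intersect(module_genes_1, module_genes_2))
  if (!length(step3)) {
    warn("strongest-module intersection is empty; disease-A set will be empty")
  }
  genes <- sorted_unique(intersect(step2, step3))

  all_seen <- sorted_unique(c(step1, step2, step3))
  provenance <- tibble(
    gene_id = all_seen,
    in_step1 = all_seen %in% step1,
    in_step2 = all_seen %in% step2,
    in_step3 = all_seen %in% step3,
    retained = all_seen %in% genes
  )
  structure(
    list(
      genes = genes,
      steps = list(step1 = step1, step2 = step2, step3 = step3),
      provenance = provenance
    ),
    class = "disease_a_set"
  )
}

#' @export
print.disease_a_set <- function(x, ...) {
  cat(sprintf(
    "<disease_a_set> %d genes (steps: %d -> %d consistent, %d module-shared)\n",
    length(x$genes), length(x$steps$step1), length(x$steps$step2),
    length(x$steps$step3)
  ))
  invisible(x)
}

#' Common hub genes of the two diseases
#'
#' @param set_a,set_b Character vectors of disease gene ids.
#' @return The sorted intersection.
#' @export
common_hubs <- function(set_a, set_b) {
  sorted_unique(intersect(set_a, set_b))
}

#' Write a derived gene set with its provenance record
#'
#' The set goes to `<stem>.txt` (one gene per line) and the provenance to
#' `<stem>_provenance.json`.
#'
#' @param set A `disease_a_set` or plain character vector.
#' @param stem Path stem (no extension).
#' @export
write_gene_set <- function(set, stem) {
  genes <- if (inherits(set, "disease_a_set")) set$genes else set
  write_gene_list(genes, paste0(stem, ".txt"))
  if (inherits(set, "disease_a_set")) {
    jsonlite::write_json(set$provenance, paste0(stem, "_provenance.json"),
      dataframe = "rows", auto_unbox = TRUE
    )
  }
  invisible(stem)
}
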