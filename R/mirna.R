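#' Shared miRNAs between two disease lists
#'
#' Identifiers are normalized (lowercase, whitespace trimmed) before
#' intersection; the sorted normalized intersection is returned.
#'
#' @param list_a,list_b Character vectors of miRNA ids.
#' @return Sorted character vector.
#' @export
shared_mirnas <- function(list_a, list_b) {
  norm <- function(x) tolower(trimws(x))
  sorted_unique(intersect(norm(list_a), norm(list_b)))
}

#' miRNA-to-hub-gene edges
#'
#' Restricts each shared miRNA's targets to the common hub genes. miRNAs
#' with no hub target contribute no edge but are reported in the
#' `unconnected` attribute.
#'
#' @param shared Character vector of shared miRNA ids.
#' @param target_map Tibble with columns `mirna`, `target`.
#' @param hubs Character vector of common hub genes.
#' @return A tibble with columns `mirna`, `gene` (attribute `unconnected`
#'   lists miRNAs without hub targets).
#' @export
hub_targets <- function(shared, target_map, hubs) {
  if (!all(c("mirna", "target") %in% names(target_map))) {
    abort("`target_map` needs columns mirna and target")
  }
  norm <- function(x) tolower(trimws(x))
  shared <- sorted_unique(norm(shared))
  tm <- target_map
  tm$mirna <- norm(tm$mirna)
  tm <- tm[tm$mirna %in% shared & tm$target %in% hubs, , drop = FALSE]
  edges <- distinct(tibble(mirna = tm$mirna, gene = tm$target)) |>
    arrange(.data$mirna, .data$gene)
  attr(edges, "unconnected") <- setdiff(shared, edges$mirna)
  edges
}

#' Assemble the disease-miRNA-gene regulatory network
#'
#' Builds a typed graph with `disease` nodes linked to every shared miRNA
#' and `mirna -> gene` edges from [hub_targets()]. The miRNA/gene layers
#' are bipartite by construction.
#'
#' @param shared Shared miRNA ids.
#' @param edges Tibble from [hub_targets()].
#' @param diseases Names of the two disease nodes.
#' @return An igraph with vertex attribute `type` in
#'   `{disease, mirna, gene}`.
#' @export
build_regulatory_network <- function(shared, edges,
                                     diseases = c("disease_A", "disease_B")) {
  shared <- sorted_unique(tolower(trimws(shared)))
  genes <- sorted_unique(edges$gene)
  el <- rbind(
    as.matrix(expand.grid(diseases, shared, stringsAsFactors = FALSE)),
    cbind(edges$mirna, edges$gene)
  )
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(diseases) + length(shared) + length(genes),
    name = c(diseases, shared, genes),
    type = c(
      rep("disease", length(diseases)),
      rep("mirna", length(shared)),
      rep("gene", length(genes))
    )
  )
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  g
}

#' Export a regulatory network as SIF or GraphML
#'
#' SIF edges are labelled by the endpoint types (`disease-mirna` /
#' `mirna-gene`); GraphML preserves the `type` vertex attribute, making the
#' round trip lossless.
#'
#' @param net igraph from [build_regulatory_network()].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- arg_match(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    types <- setNames(igraph::V(net)$type, igraph::V(net)$name)
    rel <- if (nrow(el)) paste(types[el[, 1]], types[el[, 2]], sep = "-") else character()
    write_sif(
      tibble(
        node1 = el[, 1], interaction = rel,
        node2 = el[, 2]
      ),
      path
    )
  }
  invisible(path)
}
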