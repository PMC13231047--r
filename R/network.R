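#' Load a scored interaction network from an edge table or SIF file
#'
#' Combined scores on the 0-1000 integer scale are divided by 1000; edges
#' below `min_score` (on the 0-1 scale, inclusive threshold) are dropped,
#' self-loops removed, duplicate edges collapsed to their maximum score,
#' and isolated nodes discarded.
#'
#' @param edges Path to a TSV with columns `node1`, `node2`,
#'   `combined_score`, a path to a SIF file, or an in-memory tibble of the
#'   same shape.
#' @param min_score Minimum combined score on the 0-1 scale (default 0.4).
#' @param sif_score Score (0-1000) assigned to SIF edges, which carry none.
#' @return An undirected simple igraph with edge attribute `score` in
#'   `[0, 1]`.
#' @export
load_network <- function(edges, min_score = 0.4, sif_score = 1000) {
  if (is.character(edges) && length(edges) == 1) {
    if (grepl("\\.sif$", edges, ignore.case = TRUE)) {
      sif <- read_sif(edges)
      edges <- tibble(
        node1 = sif$node1, node2 = sif$node2,
        combined_score = rep(sif_score, nrow(sif))
      )
    } else {
      edges <- read_edge_table(edges)
    }
  }
  if (!all(c("node1", "node2", "combined_score") %in% names(edges))) {
    abort("`edges` needs columns node1, node2, combined_score")
  }
  if (nrow(edges) && any(edges$combined_score > 1000)) {
    abort("combined_score above 1000: unknown score scale")
  }
  if (nrow(edges) && any(edges$combined_score < 0)) {
    abort("negative combined_score")
  }
  edges$score <- edges$combined_score / 1000
  edges <- edges[edges$score >= min_score & edges$node1 != edges$node2, , drop = FALSE]
  # collapse duplicates (either orientation) keeping the max score
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  df <- tibble(from = a, to = b, score = edges$score) |>
    group_by(.data$from, .data$to) |>
    summarise(score = max(.data$score), .groups = "drop")
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g
}

#' Degree, betweenness, and closeness centralities with above-average flags
#'
#' Betweenness is unweighted shortest-path betweenness normalized by
#' `(n - 1)(n - 2) / 2`. Closeness is computed within each connected
#' component and rescaled by `(n_c - 1) / (n - 1)` (Wasserman-Faust), so
#' values are comparable across components. A node is flagged
#' `above_average` iff all three values strictly exceed their network-wide
#' means.
#'
#' @param net An undirected igraph.
#' @return A tibble of class `centrality_table` with columns `node`,
#'   `degree`, `betweenness`, `closeness`, `above_average`.
#' @export
centralities <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3) abort("need at least 3 nodes for centrality analysis")
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  d <- igraph::distances(net)
  comp <- igraph::components(net)$membership
  clo <- vapply(seq_len(n), function(i) {
    same <- comp == comp[i]
    nc <- sum(same)
    if (nc < 2) {
      return(0)
    }
    ((nc - 1) / sum(d[i, same])) * ((nc - 1) / (n - 1))
  }, numeric(1))
  out <- tibble(
    node = igraph::V(net)$name,
    degree = as.numeric(deg),
    betweenness = as.numeric(btw),
    closeness = clo
  )
  out$above_average <- out$degree > mean(out$degree) &
    out$betweenness > mean(out$betweenness) &
    out$closeness > mean(out$closeness)
  class(out) <- c("centrality_table", class(out))
  out
}

#' MCODE cluster score (density times node count)
#'
#' `score = (2 m / (n (n - 1))) * n`, reported to three decimals.
#'
#' @param n Node count (>= 2).
#' @param m Edge count (0 to `choose(n, 2)`).
#' @return The score, rounded to 3 decimals.
#' @export
#' @examples
#' cluster_score(29, 316)
#' cluster_score(59, 1424)
cluster_score <- function(n, m) {
  if (n < 2) abort("cluster score needs n >= 2")
  if (m < 0 || m > choose(n, 2)) abort("edge count out of range")
  round((2 * m / (n * (n - 1))) * n, 3)
}

#' MCODE molecular-complex detection
#'
#' The staged complex-detection algorithm: (1) vertex weighting — each node
#' of degree >= `degree_cutoff` is weighted by the density of the
#' highest-k-core of its closed neighborhood times that core's `k`; lower
#' degree nodes get weight 0. (2) complex prediction — seeds are unvisited
#' nodes in decreasing weight order; neighbours are included breadth-first
#' while their weight is at least `seed_weight * (1 - node_score_cutoff)`
#' and they are unvisited. (3) post-processing — complexes lacking a
#' `k_core` are discarded and, with `haircut`, degree-1 members are removed
#' iteratively. Complexes are scored density x node count and ranked
#' descending (ties broken by seed node id).
#'
#' @param net Undirected simple igraph.
#' @param degree_cutoff Minimum degree for a nonzero vertex weight.
#' @param k_core Core level a surviving complex must contain (default 2).
#' @param node_score_cutoff Inclusion slack relative to the seed weight.
#' @param haircut Iteratively strip degree-1 members?
#' @param fluff Unsupported (must stay `FALSE`; the published default).
#' @return A tibble of class `mcode_result`: `cluster`, `seed`, `n_nodes`,
#'   `n_edges`, `score`, `members` (list column), ranked by score.
#' @export
mcode <- function(net, degree_cutoff = 2, k_core = 2, node_score_cutoff = 0.2,
                  haircut = TRUE, fluff = FALSE) {
  if (fluff) abort("the fluff stage is not implemented (published default: false)")
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v))

  # stage 1: vertex weighting by core-clustering coefficient
  w <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    if (deg[i] < degree_cutoff) next
    nb <- c(i, adj[[i]])
    sub <- igraph::induced_subgraph(net, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_nodes <- which(core == kmax)
    if (length(core_nodes) < 2) next
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    nn <- igraph::vcount(core_sub)
    dens <- 2 * igraph::ecount(core_sub) / (nn * (nn - 1))
    w[i] <- dens * kmax
  }

  # stage 2: greedy complex prediction from heaviest unvisited seeds
  visited <- logical(length(nodes))
  complexes <- list()
  seeds <- character()
  ord <- order(-w, nodes)
  for (s in ord) {
    if (visited[s] || w[s] <= 0) next
    threshold <- w[s] * (1 - node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    queue <- adj[[s]]
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (visited[v] || w[v] < threshold) next
      visited[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, adj[[v]])
    }
    if (length(members) >= 2) {
      complexes[[length(complexes) + 1]] <- members
      seeds <- c(seeds, nodes[s])
    }
  }

  # stage 3: k-core check and haircut
  out <- list()
  for (ci in seq_along(complexes)) {
    sub <- igraph::induced_subgraph(net, complexes[[ci]])
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    if (haircut) {
      repeat {
        dg <- igraph::degree(sub)
        drop <- which(dg < 2)
        if (!length(drop) || length(drop) == igraph::vcount(sub)) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    nn <- igraph::vcount(sub)
    if (nn < 2) next
    mm <- igraph::ecount(sub)
    out[[length(out) + 1]] <- tibble(
      seed = seeds[ci],
      n_nodes = nn,
      n_edges = mm,
      score = cluster_score(nn, mm),
      members = list(sorted_unique(igraph::V(sub)$name))
    )
  }
  if (!length(out)) {
    res <- tibble(
      cluster = integer(), seed = character(), n_nodes = integer(),
      n_edges = integer(), score = numeric(), members = list()
    )
  } else {
    res <- bind_rows(out) |>
      arrange(desc(.data$score), .data$seed) |>
      mutate(cluster = row_number(), .before = 1)
  }
  class(res) <- c("mcode_result", class(res))
  res
}

#' Maximal clique centrality ranking
#'
#' `MCC(v)` is the sum over all maximal cliques containing `v` of
#' `(clique size - 1)!`. Maximal cliques are enumerated with the pivoting
#' Bron-Kerbosch algorithm. For a node whose neighborhood has no internal
#' edges every incident edge is itself a maximal 2-clique, so the formula
#' yields the node's degree. Nodes are ranked by MCC descending, ties
#' broken by node id; the top `top_n` are flagged, and ties crossing the
#' rank-`top_n` boundary are all included (with a warning).
#'
#' @param net Undirected simple igraph.
#' @param top_n Number of top nodes to flag (default 20).
#' @param max_cliques Enumeration budget; exceeded -> error (default 1e6).
#' @return A tibble of class `mcc_ranking`: `node`, `mcc`, `rank`, `top`.
#' @export
mcc <- function(net, top_n = 20, max_cliques = 1e6) {
  n_cl <- igraph::count_max_cliques(net, min = 2)
  if (n_cl > max_cliques) {
    abort(sprintf(
      "%d maximal cliques exceed the budget of %g; retry on a degeneracy-ordered or pre-filtered graph",
      n_cl, max_cliques
    ))
  }
  cliques <- igraph::max_cliques(net, min = 2)
  score <- setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  for (cl in cliques) {
    contrib <- factorial(length(cl) - 1)
    ids <- igraph::V(net)$name[as.integer(cl)]
    score[ids] <- score[ids] + contrib
  }
  out <- tibble(node = names(score), mcc = unname(score)) |>
    arrange(desc(.data$mcc), .data$node) |>
    mutate(rank = row_number())
  if (nrow(out) > top_n) {
    cut <- out$mcc[top_n]
    out$top <- out$mcc > cut | (out$mcc == cut & out$rank <= top_n)
    tied <- out$mcc == cut
    if (sum(tied & out$top) < sum(tied)) {
      # include all nodes tied at the boundary to keep selection order-free
      out$top[tied] <- TRUE
      warn(sprintf(
        "MCC rank-%d boundary tie: flagging %d nodes", top_n, sum(out$top)
      ))
    }
  } else {
    out$top <- TRUE
  }
  class(out) <- c("mcc_ranking", class(out))
  out
}

#' Triangulate key hub genes from the three network analyses
#'
#' The intersection of (i) nodes above average on all three centralities,
#' (ii) members of the top-scoring MCODE complex, and (iii) the MCC
#' top-ranked nodes.
#'
#' @param cent A [centralities()] table.
#' @param mcode_res An [mcode()] result (its top cluster is used).
#' @param mcc_rank An [mcc()] ranking.
#' @return Sorted character vector of key hub genes.
#' @export
triangulate_hubs <- function(cent, mcode_res, mcc_rank) {
  topo <- cent$node[cent$above_average]
  top_cluster <- if (nrow(mcode_res)) mcode_res$members[[1]] else character()
  mcc_top <- mcc_rank$node[mcc_rank$top]
  sorted_unique(Reduce(intersect, list(topo, top_cluster, mcc_top)))
}

#' Write an annotated network as GraphML
#'
#' @param net igraph object.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
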