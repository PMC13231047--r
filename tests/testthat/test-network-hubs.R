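edge_tbl <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(
    node1 = m[, 1], node2 = m[, 2],
    combined_score = as.numeric(m[, 3])
  )
}

graph_from_edges <- function(...) {
  igraph::graph_from_edgelist(matrix(c(...), ncol = 2, byrow = TRUE), directed = FALSE)
}

test_that("network loading filters scores, duplicates, loops, and isolates", {
  edges <- edge_tbl(
    "a", "b", 400, # kept: threshold is inclusive
    "b", "c", 399, # dropped
    "a", "c", 500, # duplicate pair below...
    "c", "a", 700, # ...kept at the max score
    "d", "d", 900 # self loop, d disappears entirely
  )
  g <- load_network(edges, min_score = 0.4)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 2)
  eid <- igraph::get_edge_ids(g, c("a", "c"))
  expect_equal(igraph::E(g)$score[eid], 0.7)
  expect_error(load_network(edge_tbl("a", "b", 1400)), "scale")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node1\tnode2\tcombined_score", "a\tb\t500", "x\ty\t"), path)
  expect_error(load_network(path), "line")
})

test_that("SIF input loads with full scores", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a\tpp\tb", "b\tpp\tc"), path)
  g <- load_network(path)
  expect_equal(igraph::ecount(g), 2)
  expect_true(all(igraph::E(g)$score == 1))
})

test_that("centralities match closed forms on stars, paths, and cycles", {
  star <- graph_from_edges("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  cs <- centralities(star)
  centre <- cs[cs$node == "c", ]
  expect_equal(centre$degree, 4)
  expect_equal(centre$betweenness, 1) # all 6 leaf pairs route through c
  expect_true(centre$above_average)
  expect_false(any(cs$above_average[cs$node != "c"]))

  p3 <- graph_from_edges("a", "m", "m", "b")
  cp <- centralities(p3)
  expect_equal(cp$betweenness[cp$node == "m"], 1)

  c5 <- graph_from_edges("a", "b", "b", "c", "c", "d", "d", "e", "e", "a")
  cc <- centralities(c5)
  expect_true(all(!cc$above_average)) # symmetric: nobody strictly above mean
  expect_equal(length(unique(round(cc$closeness, 12))), 1)
})

test_that("closeness uses Wasserman-Faust scaling across components", {
  # K3 plus a disjoint edge: K3 nodes have within-component closeness 1,
  # scaled by (3-1)/(5-1); the pair by (2-1)/(5-1)
  g <- graph_from_edges("a", "b", "b", "c", "a", "c", "x", "y")
  cs <- centralities(g)
  expect_equal(cs$closeness[cs$node == "a"], 2 / 4)
  expect_equal(cs$closeness[cs$node == "x"], 1 / 4)
  # agrees with igraph's normalized closeness on a connected graph
  p4 <- graph_from_edges("a", "b", "b", "c", "c", "d")
  cs4 <- centralities(p4)
  ig <- igraph::closeness(p4, normalized = TRUE)
  expect_equal(cs4$closeness, unname(ig[cs4$node]), tolerance = 1e-12)
})

test_that("MCODE recovers the dense core and applies post-processing", {
  # K5 with a pendant vertex: top cluster is the K5, score 5.0
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  g <- igraph::add_vertices(k5, 1, name = "pendant")
  g <- igraph::add_edges(g, c("k1", "pendant"))
  res <- mcode(g)
  expect_equal(res$n_nodes[1], 5)
  expect_equal(res$n_edges[1], 10)
  expect_equal(res$score[1], 5.0)
  expect_setequal(res$members[[1]], paste0("k", 1:5))

  tri <- graph_from_edges("a", "b", "b", "c", "c", "a")
  res_tri <- mcode(tri)
  expect_equal(res_tri$score[1], 3.0)

  tree <- graph_from_edges("r", "a", "r", "b", "a", "c", "a", "d")
  expect_equal(nrow(mcode(tree)), 0) # no 2-core anywhere
})

test_that("MCODE is deterministic under vertex relabeling", {
  g <- random_graph(25, 0.25, seed = 5)
  res1 <- mcode(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  res2 <- mcode(g2)
  expect_equal(res1$score, res2$score)
  expect_equal(
    lapply(res1$members, sort),
    lapply(res2$members, sort)
  )
})

test_that("cluster score reproduces the published worked examples", {
  expect_equal(cluster_score(29, 316), 22.571)
  expect_equal(cluster_score(59, 1424), 49.103)
  expect_equal(cluster_score(3, 3), 3.000)
  for (n in c(2, 5, 9, 17)) {
    expect_equal(cluster_score(n, choose(n, 2)), n) # complete graphs
  }
  expect_error(cluster_score(1, 0), "n >= 2")
  expect_error(cluster_score(4, 7), "out of range")
})

test_that("MCC matches hand values on cliques and paths", {
  tri <- graph_from_edges("a", "b", "b", "c", "c", "a")
  r <- mcc(tri)
  expect_true(all(r$mcc == 2)) # one maximal 3-clique, (3-1)! = 2
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_true(all(mcc(k4)$mcc == 6))
  p3 <- graph_from_edges("a", "m", "m", "b")
  rp <- mcc(p3)
  expect_equal(rp$mcc[rp$node == "m"], 2) # two maximal 2-cliques
  expect_equal(rp$mcc[rp$node == "a"], 1) # degree for edgeless neighborhoods
})

test_that("MCC equals the exhaustive maximal-clique oracle on random graphs", {
  for (seed in 1:20) {
    n <- sample(6:12, 1)
    g <- random_graph(n, runif(1, 0.2, 0.7), seed = seed)
    am <- as.matrix(igraph::as_adjacency_matrix(g))
    expected <- brute_mcc(am)
    got <- mcc(g)
    expect_equal(
      setNames(got$mcc, got$node)[names(expected)],
      expected
    )
  }
})

test_that("MCC flags boundary ties inclusively", {
  # two disjoint triangles + path: all triangle nodes tie
  g <- graph_from_edges(
    "a", "b", "b", "c", "c", "a",
    "d", "e", "e", "f", "f", "d"
  )
  expect_warning(r <- mcc(g, top_n = 4), "tie")
  expect_equal(sum(r$top), 6)
})

test_that("triangulation intersects all three node sets", {
  cent <- tibble::tibble(
    node = c("a", "b", "c", "d"),
    degree = 1, betweenness = 1, closeness = 1,
    above_average = c(TRUE, TRUE, FALSE, TRUE)
  )
  mcode_res <- tibble::tibble(
    cluster = 1L, seed = "a", n_nodes = 3L, n_edges = 3L, score = 3,
    members = list(c("a", "b", "c"))
  )
  mcc_rank <- tibble::tibble(
    node = c("a", "b", "c", "d"),
    mcc = c(4, 3, 2, 1), rank = 1:4,
    top = c(TRUE, FALSE, TRUE, TRUE)
  )
  # b fails only MCC, c fails only centrality, d fails only MCODE
  expect_equal(triangulate_hubs(cent, mcode_res, mcc_rank), "a")
})

test_that("a wired super-hub survives triangulation on synthetic networks", {
  for (seed in 1:10) {
    set.seed(seed)
    # dense planted module plus sparse background; the super-hub is wired
    # to the whole module and bridges it to the background
    module <- igraph::sample_gnp(20, 0.85)
    igraph::V(module)$name <- sprintf("m%02d", 1:20)
    g <- igraph::disjoint_union(module, {
      bg <- igraph::sample_gnp(30, 0.05)
      igraph::V(bg)$name <- sprintf("b%02d", 1:30)
      bg
    })
    g <- igraph::add_vertices(g, 1, name = "superhub")
    g <- igraph::add_edges(g, as.vector(rbind("superhub", sprintf("m%02d", 1:20))))
    g <- igraph::add_edges(g, as.vector(rbind("superhub", sprintf("b%02d", 1:3))))
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    key <- suppressWarnings(
      triangulate_hubs(centralities(g), mcode(g), mcc(g))
    )
    expect_true("superhub" %in% key)
  }
})
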