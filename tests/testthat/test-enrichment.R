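test_that("ORA reproduces exact hypergeometric probabilities", {
  universe <- sprintf("u%02d", 1:20)
  term <- universe[1:5]
  res <- ora(universe[1:5], list(hit = term), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12) # 1/15504
  # zero overlap: upper tail includes k = 0, so p = 1
  res0 <- ora(universe[6:10], list(miss = term), universe)
  expect_equal(res0$p, 1)
  # query equal to the universe: every term fully hit, p = 1
  resU <- ora(universe, list(t1 = term, t2 = universe[6:7]), universe)
  expect_true(all(resU$p == 1))
  expect_true(all(resU$k == resU$K))
  expect_warning(
    ora(c(universe[1], "outside"), list(t = term), universe),
    "outside the universe"
  )
  expect_error(
    suppressWarnings(ora("outside", list(t = term), universe)),
    "empty query"
  )
})

test_that("ORA p-values match the pmf-summation oracle on random cases", {
  set.seed(1)
  for (i in 1:50) {
    N <- sample(8:30, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    universe <- sprintf("g%03d", 1:N)
    query <- sample(universe, n)
    term <- sample(universe, K)
    res <- ora(query, list(t = term), universe)
    k <- length(intersect(query, term))
    expect_equal(res$p, brute_hyper_upper(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("shared top terms intersect the leading entries of both rankings", {
  mk <- function(sets) {
    tibble::tibble(
      set = sets, k = 1, K = 1, n = 1, N = 10,
      p = seq_along(sets) / 100, adj_p = seq_along(sets) / 100,
      significant = TRUE
    )
  }
  a <- mk(sprintf("T%02d", 1:30))
  b <- mk(sprintf("T%02d", c(3, 1, 40:60)))
  expect_equal(shared_terms(a, b, top_n = 20), c("T01", "T03"))
  expect_equal(shared_terms(a, mk(sprintf("X%02d", 1:25))), character(0))
})

test_that("GSEA running-sum extremum matches the naive full-scan oracle", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    ranked <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    set <- sample(names(ranked), sample(3:10, 1))
    for (w in c(0, 1)) {
      fast <- comorbhub:::gsea_es(
        sort(ranked, decreasing = TRUE),
        names(sort(ranked, decreasing = TRUE)) %in% set, w
      )
      expect_equal(fast, brute_gsea_es(ranked, set, w), tolerance = 1e-12)
    }
  }
})

test_that("GSEA ES agrees with the fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(3)
  ranked <- sort(setNames(rnorm(100), sprintf("g%03d", 1:100)), decreasing = TRUE)
  set <- sample(names(ranked), 15)
  mine <- comorbhub:::gsea_es(ranked, names(ranked) %in% set, 1)
  ref <- fgsea::calcGseaStat(
    stats = ranked, selectedStats = which(names(ranked) %in% set),
    gseaParam = 1, scoreType = "std"
  )
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("a set of exactly the top-ranked genes maximizes the ES", {
  ranked <- setNames(seq(5, 0.1, length.out = 100), sprintf("g%03d", 1:100))
  res <- gsea(ranked, names(ranked)[1:10], n_perm = 1000, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lt(res$p, 0.005)
  expect_gt(res$nes, 1)
})

test_that("GSEA p-values are uniform under random gene sets", {
  ranked <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  ranked <- sort(ranked, decreasing = TRUE)
  set.seed(4)
  pvals <- vapply(1:200, function(i) {
    gsea(ranked, sample(names(ranked), 10), n_perm = 199, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("weight zero gives the classic unweighted KS statistic", {
  ranked <- setNames(c(10, 5, 2, 1, 0.5, 0.1), letters[1:6])
  # with w = 0 every hit contributes 1/Nh regardless of score
  es <- comorbhub:::gsea_es(ranked, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), 0)
  expect_equal(es, 0.5 + 0.5 - 1 / 4 - 0 / 4 - 0) # running max at position 3
})

test_that("ssGSEA scores are rank-based and monotone in set placement", {
  set.seed(5)
  expr <- matrix(runif(50 * 8, 1, 100), 50, 8,
    dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8))
  )
  top_gene <- rownames(expr)[order(-expr[, 1])][1]
  bottom_gene <- rownames(expr)[order(-expr[, 1])][50]
  sc <- ssgsea(expr, list(top = top_gene, bottom = bottom_gene), normalize = FALSE)
  expect_gt(sc["s1", "top"], sc["s1", "bottom"])
  # invariance under strictly monotone per-sample transforms
  sets <- list(a = rownames(expr)[1:10], b = rownames(expr)[20:35])
  s0 <- ssgsea(expr, sets, normalize = FALSE)
  s1 <- ssgsea(log2(expr + 1), sets, normalize = FALSE)
  s2 <- ssgsea(exp(expr / 20), sets, normalize = FALSE)
  expect_equal(unclass(s0), unclass(s1), tolerance = 1e-12)
  expect_equal(unclass(s0), unclass(s2), tolerance = 1e-12)
  expect_warning(
    miss <- ssgsea(expr, list(gone = c("nope1", "nope2")), normalize = FALSE),
    "no genes"
  )
  expect_true(all(is.na(miss)))
  norm <- ssgsea(expr, sets)
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("infiltration contrast behaves at the null and at full separation", {
  scores <- matrix(rep(1:20 / 20, 2), 20, 2,
    dimnames = list(sprintf("s%02d", 1:20), c("ct1", "ct2"))
  )
  groups <- rep(c("case", "control"), 10)
  same <- compare_infiltration(
    matrix(rep(c(1:10 / 10, 1:10 / 10), 2), 20, 2,
      dimnames = list(sprintf("s%02d", 1:20), c("ct1", "ct2"))
    ),
    c(rep("case", 10), rep("control", 10))
  )
  expect_true(all(same$p > 0.9))
  sep <- compare_infiltration(
    matrix(c(11:20, 1:10) / 20, 20, 1,
      dimnames = list(sprintf("s%02d", 1:20), "ct")
    ),
    c(rep("case", 10), rep("control", 10))
  )
  expect_lt(sep$p, 1e-3)
  expect_equal(sep$direction, "up")
})

test_that("gene-cell correlations flag signed associations correctly", {
  set.seed(6)
  x <- rnorm(30)
  expr <- rbind(hub = x)
  colnames(expr) <- sprintf("s%02d", 1:30)
  scores <- cbind(
    mono = exp(x), # perfect monotone: rho = 1
    anti = -x^3, # reversed ranks: rho = -1
    noise = rnorm(30)
  )
  rownames(scores) <- colnames(expr)
  res <- correlate_genes_cells(expr, scores)
  expect_equal(res$rho[res$cell_type == "mono"], 1)
  expect_equal(res$rho[res$cell_type == "anti"], -1)
  expect_true(res$flagged[res$cell_type == "mono"])
  expect_false(res$flagged[res$cell_type == "anti"]) # signed rule
  res_abs <- correlate_genes_cells(expr, scores, signed = FALSE)
  expect_true(res_abs$flagged[res_abs$cell_type == "anti"])
})

test_that("null data rarely clears the joint correlation flag", {
  set.seed(7)
  expr <- rbind(hub = rnorm(50))
  colnames(expr) <- sprintf("s%02d", 1:50)
  scores <- matrix(rnorm(50 * 500), 50, 500,
    dimnames = list(colnames(expr), sprintf("ct%03d", 1:500))
  )
  res <- correlate_genes_cells(expr, scores)
  expect_lte(mean(res$flagged), 0.06)
})
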