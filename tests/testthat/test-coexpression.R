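named_matrix <- function(m) {
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))), sprintf("s%03d", seq_len(ncol(m))))
  m
}

test_that("outlier detection excludes only samples far below the mean similarity", {
  set.seed(1)
  f <- rnorm(200)
  expr <- named_matrix(sapply(1:20, function(i) f + rnorm(200, sd = 0.2)))
  rep0 <- detect_outlier_samples(expr)
  expect_false(any(rep0$excluded)) # tight cohort: nobody 3 sigma below
  for (seed in 1:5) {
    set.seed(seed)
    bad <- expr
    bad[, 20] <- sample(bad[, 20]) # destroy one sample's gene order
    rep1 <- detect_outlier_samples(bad)
    expect_true(rep1$excluded[20])
    expect_false(any(rep1$excluded[1:19]))
  }
  const <- expr
  const[, 3] <- 1
  expect_error(detect_outlier_samples(const), "s003")
})

test_that("outlier rule is strict: a sample exactly at mu - 3 sigma is kept", {
  # construct a report-level check through the exported invariant
  set.seed(2)
  expr <- named_matrix(matrix(rnorm(100 * 10), 100, 10))
  rep <- detect_outlier_samples(expr)
  at_boundary <- rep$mean_similarity == rep$mu - 3 * rep$sigma
  expect_true(all(!rep$excluded[at_boundary] | !at_boundary))
  expect_identical(rep$excluded, rep$mean_similarity < rep$mu - 3 * rep$sigma)
})

test_that("variable-gene selection ranks by MAD with lexicographic ties", {
  expr <- rbind(
    zzz = c(1, 1, 1), # MAD 0
    bbb = c(1, 2, 3), # MAD 1
    aaa = c(4, 5, 6) # MAD 1, tie with bbb -> aaa first
  )
  colnames(expr) <- c("s1", "s2", "s3")
  out <- select_variable_genes(expr, k = 3)
  expect_equal(rownames(out), c("aaa", "bbb", "zzz"))
  expect_equal(rownames(select_variable_genes(expr, k = 2)), c("aaa", "bbb"))
  expect_equal(nrow(select_variable_genes(expr, k = 10)), 3)
})

test_that("scale-free fit index is near 1 for power-law degrees, low for noise", {
  k <- 50 / seq_len(400) # p(k) ~ k^-2 exactly
  expect_gt(comorbhub:::scale_free_fit(k), 0.99)
  set.seed(3)
  expr <- named_matrix(matrix(rnorm(200 * 60), 200, 60))
  s <- abs(cor(t(expr)))
  diag(s) <- 0
  expect_lt(comorbhub:::scale_free_fit(rowSums(s)), 0.5)
})

test_that("soft-threshold scan enforces its contracts", {
  set.seed(4)
  expr <- named_matrix(matrix(rnorm(100 * 30), 100, 30))
  scan <- suppressWarnings(pick_soft_threshold(expr, powers = 1:10))
  # mean connectivity non-increasing in beta for |S| <= 1
  expect_true(all(diff(scan$scan$mean_connectivity) <= 1e-12))
  expect_error(pick_soft_threshold(expr, powers = 2), "at least 2")
  expect_error(
    pick_soft_threshold(named_matrix(matrix(rnorm(5 * 30), 5, 30))),
    "fewer genes"
  )
})

test_that("adjacency follows |cor|^beta with unit diagonal", {
  expr <- rbind(g1 = c(1, 0, 0), g2 = c(0, 1, 0))
  colnames(expr) <- c("s1", "s2", "s3")
  a2 <- adjacency_matrix(expr, beta = 2)
  expect_equal(a2["g1", "g2"], 0.25) # cor = -0.5, squared
  a1 <- adjacency_matrix(expr, beta = 1)
  expect_equal(a1["g1", "g2"], 0.5)
  expect_true(isSymmetric(a2))
  expect_true(all(a2 <= 1))
  expect_equal(unname(diag(a2)), c(1, 1))
  const <- rbind(g1 = c(1, 1, 1), g2 = c(0, 1, 0))
  colnames(const) <- c("s1", "s2", "s3")
  expect_error(adjacency_matrix(const, 2), "zero-variance")
})

test_that("TOM matches the hand-computed triangle and the degenerate pair", {
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tm <- tom_similarity(ones)
  expect_true(all(abs(tm$tom - 1) < 1e-12)) # (1+1)/(2+1-1) = 1
  # two genes with no adjacency and no shared neighbours
  iso <- diag(2)
  dimnames(iso) <- list(c("a", "b"), c("a", "b"))
  expect_equal(tom_similarity(iso)$tom["a", "b"], 0)
  expect_error(tom_similarity(matrix(runif(6), 2, 3)), "symmetric")
})

test_that("TOM equals the O(n^3) brute-force oracle on random adjacencies", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(30:50, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    fast <- tom_similarity(a)$tom
    slow <- brute_tom(a)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("planted blocks are recovered as exactly two modules", {
  aris <- vapply(1:5, function(seed) {
    cfg <- small_config(
      seed = seed, n_genes = 200, module_sizes = c(100L, 100L),
      module_latent_cor = 0.8, de_effect_log2 = 0, n_background_de = 1,
      n_case = list(a = c(50L, 4L), b = c(4L, 4L)),
      n_control = list(a = c(50L, 4L), b = c(4L, 4L)),
      n_assoc_genes = 100, n_planted_hubs = 6
    )
    sim <- generate_expression(cfg)
    expr <- sim$cohorts$a1$expr # 100 samples
    fit <- suppressWarnings(run_coexpression(expr, setNames(
      as.numeric(sim$cohorts$a1$pheno$group == "case"),
      sim$cohorts$a1$pheno$sample
    )))
    truth_mod <- sim$truth$module_membership[fit$assignment$gene_id]
    found <- setdiff(unique(fit$assignment$module), 0L)
    expect_equal(length(found), 2)
    acc <- max(
      mean((truth_mod == 1) == (fit$assignment$module == found[1])),
      mean((truth_mod == 1) == (fit$assignment$module == found[2]))
    )
    expect_gte(acc, 0.95)
    adjusted_rand(truth_mod, fit$assignment$module)
  }, numeric(1))
  expect_true(all(aris >= 0.8))
})

test_that("degenerate dissimilarities give one module or all grey", {
  z <- matrix(0, 50, 50, dimnames = list(sprintf("g%02d", 1:50), sprintf("g%02d", 1:50)))
  one <- detect_modules(z, min_module_size = 30)
  expect_equal(unique(one$module), 1L)
  # independent genes: everything stays unassigned
  set.seed(7)
  expr <- named_matrix(matrix(rnorm(100 * 60), 100, 60))
  adj <- adjacency_matrix(expr, 6)
  dd <- tom_similarity(adj)$dissimilarity
  grey <- detect_modules(dd, min_module_size = 30)
  expect_equal(unique(grey$module), 0L)
})

test_that("module eigengenes align with the module profile and latent factor", {
  set.seed(8)
  base <- rnorm(30)
  expr <- named_matrix(rbind(
    matrix(rep(base, 5), 5, byrow = TRUE), # identical genes
    matrix(rnorm(5 * 30), 5, 30)
  ))
  assign <- tibble::tibble(
    gene_id = rownames(expr),
    module = rep(1:2, each = 5)
  )
  me <- module_eigengenes(expr, assign)
  expect_equal(abs(cor(me["ME1", ], base)), 1, tolerance = 1e-10)
  # flipping every module gene flips the eigengene deterministically
  flipped <- expr
  flipped[1:5, ] <- -flipped[1:5, ]
  me2 <- module_eigengenes(flipped, assign)
  expect_equal(abs(cor(me["ME1", ], me2["ME1", ])), 1, tolerance = 1e-10)
  # planted factor recovery at rho = 0.8
  cfg <- small_config(
    seed = 9, n_genes = 100, module_sizes = c(50L, 30L),
    de_effect_log2 = 0, n_background_de = 1,
    n_case = list(a = c(50L, 4L), b = c(4L, 4L)),
    n_control = list(a = c(50L, 4L), b = c(4L, 4L)),
    n_assoc_genes = 60
  )
  sim <- generate_expression(cfg)
  mod <- sim$truth$module_membership
  assign2 <- tibble::tibble(gene_id = names(mod), module = unname(mod))
  me3 <- module_eigengenes(sim$cohorts$a1$expr, assign2)
  profile <- rowMeans(scale(t(sim$cohorts$a1$expr[mod == 1, ])))
  expect_gte(abs(cor(me3["ME1", ], profile)), 0.9)
})

test_that("module-trait correlation picks the strongest module by |cor|", {
  set.seed(10)
  trait <- rep(c(1, 0), each = 20)
  me <- rbind(
    ME1 = trait * 0.8 + rnorm(40, sd = 0.8), # positive, moderate
    ME2 = -trait * 2 + rnorm(40, sd = 0.3) # negative, strong
  )
  colnames(me) <- sprintf("s%02d", 1:40)
  mt <- module_trait_correlation(me, trait)
  expect_equal(mt$strongest_module, "ME2")
  expect_true(all(abs(mt$table$cor) <= 1))
  # eigengene equal to trait -> correlation 1
  me_exact <- rbind(ME1 = trait)
  colnames(me_exact) <- sprintf("s%02d", 1:40)
  mt2 <- module_trait_correlation(me_exact, trait)
  expect_equal(mt2$table$cor, 1)
  expect_error(module_trait_correlation(me, rep(1, 40)), "constant")
})

test_that("independent eigengenes rarely correlate with the trait", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    trait <- rep(c(1, 0), each = 50)
    me <- rbind(ME1 = rnorm(100))
    colnames(me) <- sprintf("s%03d", 1:100)
    abs(module_trait_correlation(me, trait)$table$cor)
  }, numeric(1))
  expect_gte(mean(hits < 0.3), 0.95)
})
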