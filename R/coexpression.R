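#' Flag outlier samples by mean inter-sample correlation
#'
#' Computes each sample's mean Pearson correlation with all other samples
#' (over all genes), then the mean `mu` and SD `sigma` of those scores
#' across samples. A sample is excluded iff its mean similarity is strictly
#' below `mu - 3 * sigma`.
#'
#' @param expr Numeric genes x samples matrix.
#' @return A tibble of class `outlier_report` with columns `sample`,
#'   `mean_similarity`, `mu`, `sigma`, `excluded`.
#' @export
detect_outlier_samples <- function(expr) {
  check_expr(expr, "expr")
  if (ncol(expr) < 4) abort("need at least 4 samples for outlier detection")
  sds <- apply(expr, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "sample(s) with zero variance (correlation undefined): %s",
      paste(colnames(expr)[sds == 0], collapse = ", ")
    ))
  }
  cc <- cor(expr)
  mean_sim <- (colSums(cc) - 1) / (ncol(expr) - 1)
  mu <- mean(mean_sim)
  sigma <- sd(mean_sim)
  out <- tibble(
    sample = colnames(expr),
    mean_similarity = unname(mean_sim),
    mu = mu,
    sigma = sigma,
    excluded = unname(mean_sim < mu - 3 * sigma)
  )
  class(out) <- c("outlier_report", class(out))
  out
}

#' Keep the most variable genes by median absolute deviation
#'
#' Genes are ranked by MAD (median of absolute deviations from the gene
#' median, unscaled) in descending order, ties broken lexicographically by
#' gene id, and the top `k` retained. If `k` exceeds the gene count, all
#' genes are kept.
#'
#' @param expr Numeric genes x samples matrix.
#' @param k Number of genes to keep (default 5000).
#' @return The row-subset matrix, in ranked order.
#' @export
select_variable_genes <- function(expr, k = 5000) {
  check_expr(expr, "expr")
  mads <- apply(expr, 1, function(x) median(abs(x - median(x))))
  ord <- order(-mads, rownames(expr))
  expr[ord[seq_len(min(k, nrow(expr)))], , drop = FALSE]
}

#' Scan soft-threshold powers for approximate scale-free topology
#'
#' For each candidate power `beta`, connectivities
#' `k_i = sum_j |cor(i, j)|^beta` (j != i) are computed, binned into 10
#' equal-occupancy bins, and the signed fit index
#' `sign(-slope) * R^2` of the `log10(mean k)` vs `log10(frequency)`
#' regression recorded. The chosen power is the smallest scanned `beta`
#' whose fit index exceeds `r2_min`; if none qualifies, the conventional
#' sample-size-based default power for unsigned networks (9/8/7/6 for
#' `< 20`, `20-30`, `31-40`, `> 40` samples) is chosen with a warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param powers Candidate powers (default `1:20`).
#' @param r2_min Scale-free fit threshold (default 0.85).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return A list of class `soft_threshold_scan` with elements `scan`
#'   (tibble: `power`, `scale_free_r2`, `mean_connectivity`),
#'   `chosen_beta`, and `r2_min`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_min = 0.85, n_bins = 10) {
  check_expr(expr, "expr")
  if (length(powers) < 2) abort("scan at least 2 powers")
  if (nrow(expr) < n_bins) abort("fewer genes than connectivity bins")
  s <- abs(cor(t(expr)))
  diag(s) <- 0
  scan <- purrr::map_dfr(powers, function(beta) {
    k <- rowSums(s^beta)
    tibble(
      power = beta,
      scale_free_r2 = scale_free_fit(k, n_bins),
      mean_connectivity = mean(k)
    )
  })
  hit <- scan$power[scan$scale_free_r2 > r2_min]
  if (length(hit)) {
    chosen <- hit[1]
  } else {
    # no scale-free power: use the standard sample-size-based default for
    # unsigned networks rather than chasing a plateau on a flat scan
    chosen <- min(max(powers), fallback_power(ncol(expr)))
    warn(sprintf(
      "no power reached scale-free R^2 > %.2f; falling back to the sample-size default power %s",
      r2_min, chosen
    ))
  }
  structure(
    list(scan = scan, chosen_beta = chosen, r2_min = r2_min),
    class = "soft_threshold_scan"
  )
}

# Conventional default soft-threshold power for unsigned networks when no
# scanned power reaches the scale-free fit target, by sample size.
fallback_power <- function(n_samples) {
  if (n_samples < 20) {
    9L
  } else if (n_samples <= 30) {
    8L
  } else if (n_samples <= 40) {
    7L
  } else {
    6L
  }
}

# Signed scale-free fit index from a connectivity vector.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) {
    return(NA_real_)
  }
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) {
    return(NA_real_)
  }
  bins <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bins, mean)
  # equal-occupancy bins: estimate p(k) as a density (count / bin width),
  # otherwise the counts are constant by construction
  counts <- tapply(k, bins, length)
  widths <- diff(breaks)
  pk <- counts / (length(k) * widths)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 3) {
    return(NA_real_)
  }
  x <- log10(dk[ok])
  y <- log10(pk[ok])
  if (sd(x) == 0 || sd(y) == 0) {
    return(NA_real_)
  }
  r <- cor(x, y) # slope sign equals sign(r); R^2 = r^2
  unname(-sign(r) * r^2)
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<soft_threshold_scan> %d powers scanned; chosen beta = %d\n",
    nrow(x$scan), x$chosen_beta
  ))
  invisible(x)
}

#' @method tidy soft_threshold_scan
#' @export
tidy.soft_threshold_scan <- function(x, ...) x$scan

#' Scale-free fit and connectivity across scanned powers
#'
#' @param object A [pick_soft_threshold()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soft_threshold_scan
#' @export
autoplot.soft_threshold_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scan, -"power",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$power, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_beta, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Soft-thresholded adjacency matrix
#'
#' `a_ij = |cor(i, j)|^beta` with unit diagonal (unsigned network).
#'
#' @param expr Numeric genes x samples matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return A symmetric gene x gene matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, beta) {
  check_expr(expr, "expr")
  if (beta < 1) abort("`beta` must be >= 1")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "zero-variance gene(s): %s",
      paste(head(rownames(expr)[sds == 0], 5), collapse = ", ")
    ))
  }
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over `u` distinct from `i` and `j`, `k_i = sum_{u != i} a_iu`,
#' and unit diagonal.
#'
#' @param adj Symmetric adjacency with entries in `[0, 1]` and unit
#'   diagonal.
#' @return A list with `tom` (similarity) and `dissimilarity` (`1 - tom`).
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || !isSymmetric(unname(adj), tol = 1e-10)) {
    abort("`adj` must be a symmetric matrix")
  }
  if (any(adj < 0 | adj > 1)) abort("adjacency entries must lie in [0, 1]")
  diag(adj) <- 1
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  shared <- adj %*% adj - 2 * adj # sum_{u != i,j} a_iu a_uj (uses diag 1)
  num <- shared + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissimilarity = 1 - tom)
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity, cut at a
#' static height; clusters smaller than `min_module_size` are pooled into
#' module 0 (unassigned/grey). Surviving modules are renumbered by size,
#' largest first.
#'
#' @param dissim Square dissimilarity matrix (`1 - TOM`).
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Static tree-cut height (default 0.99).
#' @return A tibble with columns `gene_id` and `module` (integer; 0 =
#'   unassigned).
#' @export
detect_modules <- function(dissim, min_module_size = 30, cut_height = 0.99) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim)) {
    abort("`dissim` must be a square matrix")
  }
  tree <- hclust(stats::as.dist(dissim), method = "average")
  raw <- cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) lab[raw == as.integer(keep[i])] <- i
  }
  tibble(gene_id = rownames(dissim), module = lab)
}

#' Module eigengenes (first principal component per module)
#'
#' The eigengene of a module is the first principal-component score vector
#' of its standardized genes x samples submatrix (samples as observations),
#' sign-aligned so its correlation with the module's mean expression
#' profile is positive.
#'
#' @param expr Numeric genes x samples matrix.
#' @param assignment Tibble from [detect_modules()].
#' @return A module x sample matrix of eigengene scores (rownames
#'   `ME<module>`).
#' @export
module_eigengenes <- function(expr, assignment) {
  check_expr(expr, "expr")
  mods <- sort(setdiff(unique(assignment$module), 0L))
  if (!length(mods)) abort("no non-grey modules to summarize")
  me <- matrix(NA_real_, length(mods), ncol(expr),
    dimnames = list(paste0("ME", mods), colnames(expr))
  )
  for (i in seq_along(mods)) {
    genes <- assignment$gene_id[assignment$module == mods[i]]
    if (length(genes) < 2) abort("each module needs >= 2 genes")
    sub <- t(scale(t(expr[genes, , drop = FALSE])))
    pc <- prcomp(t(sub), center = FALSE, scale. = FALSE)
    score <- pc$x[, 1]
    profile <- colMeans(sub)
    if (cor(score, profile) < 0) score <- -score
    me[i, ] <- score
  }
  me
}

#' Correlate module eigengenes with a binary trait
#'
#' Pearson correlation per module with a two-sided t-based p-value; the
#' strongest module maximizes the absolute correlation.
#'
#' @param eigengenes Module x sample matrix from [module_eigengenes()].
#' @param trait Numeric 0/1 vector per sample (or named vector matched to
#'   columns).
#' @return A list of class `module_trait` with `table` (tibble: `module`,
#'   `cor`, `p`) and `strongest_module`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (!is.null(names(trait))) trait <- trait[colnames(eigengenes)]
  trait <- as.numeric(trait)
  if (length(trait) != ncol(eigengenes)) {
    abort("`trait` must supply one value per sample")
  }
  if (sd(trait) == 0) abort("`trait` is constant; correlation undefined")
  n <- length(trait)
  tab <- purrr::map_dfr(rownames(eigengenes), function(m) {
    r <- cor(eigengenes[m, ], trait)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    tibble(module = m, cor = r, p = 2 * pt(-abs(tt), df = n - 2))
  })
  structure(
    list(
      table = tab,
      strongest_module = tab$module[which.max(abs(tab$cor))]
    ),
    class = "module_trait"
  )
}

#' @method tidy module_trait
#' @export
tidy.module_trait <- function(x, ...) x$table

#' @export
print.module_trait <- function(x, ...) {
  cat(sprintf(
    "<module_trait> %d modules; strongest = %s (cor = %.3f)\n",
    nrow(x$table), x$strongest_module,
    x$table$cor[x$table$module == x$strongest_module]
  ))
  invisible(x)
}

#' Module-trait correlation heatmap strip
#'
#' @param object A [module_trait_correlation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_trait
#' @export
autoplot.module_trait <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = "trait", y = .data$module, fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(p=%.1e)", .data$cor, .data$p)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cor") +
    ggplot2::theme_minimal()
}

#' Run the full co-expression stage
#'
#' Outlier exclusion, variable-gene selection, soft-threshold scan,
#' adjacency, TOM, module detection, eigengenes, and module-trait
#' correlation, in one call.
#'
#' @param expr Numeric genes x samples matrix.
#' @param trait Numeric 0/1 per sample (1 = case).
#' @param mad_top Number of MAD-ranked genes to keep.
#' @param powers,r2_min Passed to [pick_soft_threshold()].
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @return A list of class `coexpression_fit` with the outlier report, the
#'   scan, the module assignment, eigengenes, the module-trait result, and
#'   `strongest_module_genes`.
#' @export
run_coexpression <- function(expr, trait, mad_top = 5000, powers = 1:20,
                             r2_min = 0.85, min_module_size = 30,
                             cut_height = 0.99) {
  if (!is.null(names(trait))) trait <- trait[colnames(expr)]
  outliers <- detect_outlier_samples(expr)
  keep <- !outliers$excluded
  expr2 <- expr[, keep, drop = FALSE]
  trait2 <- trait[keep]
  expr2 <- select_variable_genes(expr2, k = mad_top)
  scan <- pick_soft_threshold(expr2, powers = powers, r2_min = r2_min)
  adj <- adjacency_matrix(expr2, beta = scan$chosen_beta)
  tomres <- tom_similarity(adj)
  assignment <- detect_modules(tomres$dissimilarity,
    min_module_size = min_module_size, cut_height = cut_height
  )
  me <- module_eigengenes(expr2, assignment)
  mt <- module_trait_correlation(me, trait2)
  strongest <- as.integer(sub("^ME", "", mt$strongest_module))
  structure(
    list(
      outliers = outliers,
      scan = scan,
      assignment = assignment,
      eigengenes = me,
      module_trait = mt,
      strongest_module_genes = sorted_unique(
        assignment$gene_id[assignment$module == strongest]
      )
    ),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  cat(sprintf(
    "<coexpression_fit> beta = %d; %d modules; strongest module has %d genes\n",
    x$scan$chosen_beta, length(setdiff(unique(x$assignment$module), 0L)),
    length(x$strongest_module_genes)
  ))
  invisible(x)
}
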