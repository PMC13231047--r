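#' Hypergeometric over-representation analysis
#'
#' For each term with `K` genes in the universe, of which `k` are in the
#' query of size `n` (within a universe of `N`), computes the upper-tail
#' hypergeometric probability `P(X >= k)` and Benjamini-Hochberg adjusts
#' across the collection. Query genes outside the universe are dropped with
#' a warning.
#'
#' @param query Character vector of genes.
#' @param collection Gene-set tibble as from [read_gmt()], or a named list
#'   of gene vectors.
#' @param universe Character vector of all measured genes.
#' @return A tibble of class `enrichment_result` with columns `set`, `k`,
#'   `K`, `n`, `N`, `p`, `adj_p`, `significant`, sorted by `adj_p` then `p`.
#' @export
ora <- function(query, collection, universe) {
  sets <- if (is_tibble(collection)) gmt_as_list(collection) else collection
  universe <- sorted_unique(universe)
  query0 <- sorted_unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0)) {
    warn(sprintf("%d query gene(s) outside the universe dropped", length(query0) - length(query)))
  }
  if (!length(query)) abort("empty query after restriction to the universe")
  n <- length(query)
  bigN <- length(universe)
  out <- purrr::imap_dfr(sets, function(genes, nm) {
    term <- intersect(sorted_unique(genes), universe)
    bigK <- length(term)
    k <- length(intersect(term, query))
    tibble(
      set = nm, k = k, K = bigK, n = n, N = bigN,
      p = if (bigK == 0) 1 else phyper(k - 1, bigK, bigN - bigK, n, lower.tail = FALSE)
    )
  })
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < 0.05
  out <- arrange(out, .data$adj_p, .data$p, .data$set)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Shared top-ranked enrichment terms between two analyses
#'
#' @param res_a,res_b Sorted [ora()] results.
#' @param top_n Number of leading terms considered from each list.
#' @return Sorted character vector of shared term ids.
#' @export
shared_terms <- function(res_a, res_b, top_n = 20) {
  sorted_unique(intersect(
    head(res_a$set, top_n),
    head(res_b$set, top_n)
  ))
}

#' Ranked gene-set enrichment (weighted Kolmogorov-Smirnov statistic)
#'
#' Genes are sorted by score descending. The running sum gains
#' `|score|^weight / sum(|score|^weight)` (over set members) at each hit
#' and loses `1 / (N - Nh)` at each miss; the enrichment score `es` is the
#' extremum. The null is gene-set permutation: `n_perm` same-size random
#' sets. `nes` divides `es` by the mean absolute null ES of matching sign,
#' and the p-value is the smoothed same-sign exceedance fraction
#' `(1 + #{null >= |es|}) / (1 + #same-sign null)`.
#'
#' @param ranked Named numeric vector (gene -> ranking score).
#' @param set Character vector of gene ids.
#' @param n_perm Number of permutation sets (default 1000).
#' @param weight KS weighting exponent (default 1; 0 gives the classic
#'   unweighted statistic).
#' @param seed Integer seed for the permutation null.
#' @return A tibble of class `gsea_result` with `es`, `nes`, `p`,
#'   `size`, `n_perm`; or `NULL` (with a warning) if fewer than 3 set genes
#'   are present in the ranking.
#' @export
gsea <- function(ranked, set, n_perm = 1000, weight = 1, seed = 1) {
  if (is.null(names(ranked))) abort("`ranked` must be a named vector")
  ranked <- sort(ranked, decreasing = TRUE)
  hits <- names(ranked) %in% set
  nh <- sum(hits)
  if (nh < 3) {
    warn("fewer than 3 set genes present in the ranking; set skipped")
    return(NULL)
  }
  wexp <- abs(ranked)^weight
  n <- length(ranked)
  es <- gsea_es_pos(which(hits), wexp, n)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es_pos(sort(sample.int(n, nh)), wexp, n)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  out <- tibble(
    es = es, nes = nes, p = p, size = nh, n_perm = n_perm
  )
  class(out) <- c("gsea_result", class(out))
  out
}

# Running-sum extremum for a fixed hit indicator over a sorted ranking.
gsea_es <- function(ranked, hits, weight) {
  gsea_es_pos(which(hits), abs(ranked)^weight, length(ranked))
}

# The extremum of the weighted KS running sum depends only on the hit
# positions: the maximum is attained right after a hit and the minimum just
# before one, so both are computable in O(set size).
gsea_es_pos <- function(pos, wexp, n) {
  k <- length(pos)
  w <- wexp[pos]
  sw <- sum(w)
  wcum <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  miss <- (pos - seq_len(k)) / (n - k)
  up <- wcum - miss
  down <- c(0, wcum[-k]) - miss
  mx <- max(up)
  mn <- min(down)
  if (mx >= -mn) mx else mn
}

#' GSEA over a collection with BH adjustment and the printed significance rule
#'
#' Runs [gsea()] for each set and flags significance at
#' `adj_p < 0.05 & |NES| > 1`.
#'
#' @inheritParams gsea
#' @param collection Gene-set tibble ([read_gmt()]) or named list.
#' @return A tibble with one row per scored set.
#' @export
gsea_collection <- function(ranked, collection, n_perm = 1000, weight = 1, seed = 1) {
  sets <- if (is_tibble(collection)) gmt_as_list(collection) else collection
  rows <- purrr::imap(sets, function(genes, nm) {
    r <- suppressWarnings(gsea(ranked, genes,
      n_perm = n_perm, weight = weight,
      seed = child_seed(seed, nm)
    ))
    if (is.null(r)) {
      return(NULL)
    }
    mutate(r, set = nm, .before = 1)
  })
  out <- bind_rows(rows[!vapply(rows, is.null, TRUE)])
  if (!nrow(out)) {
    return(out)
  }
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < 0.05 & abs(out$nes) > 1
  arrange(out, .data$adj_p, .data$p, .data$set)
}

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; ties get the
#' average rank). Walking down the ranking, the score accumulates the
#' difference between the rank-weighted in-set ECDF (weights
#' `rank_value^alpha`, where the top gene carries rank value `N`) and the
#' uniform out-of-set ECDF. The resulting sample x set matrix is min-max
#' normalized to `[0, 1]` across the whole matrix. Scores depend on the
#' expression values only through their ranks.
#'
#' @param expr Numeric genes x samples matrix.
#' @param collection Gene-set tibble ([read_gmt()]) or named list; sets
#'   with no overlap with the measured genes are reported as missing (NA)
#'   with a warning.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Min-max normalize the score matrix (default TRUE).
#' @return A sample x set numeric matrix of class `ssgsea_scores`.
#' @export
ssgsea <- function(expr, collection, alpha = 0.25, normalize = TRUE) {
  check_expr(expr, "expr")
  sets <- if (is_tibble(collection)) gmt_as_list(collection) else collection
  genes <- rownames(expr)
  n <- length(genes)
  member <- lapply(sets, function(g) genes %in% g)
  empty <- vapply(member, function(m) !any(m), TRUE)
  if (any(empty)) {
    warn(sprintf(
      "%d set(s) share no genes with the expression matrix; scores set to NA",
      sum(empty)
    ))
  }
  scores <- matrix(NA_real_, ncol(expr), length(sets),
    dimnames = list(colnames(expr), names(sets))
  )
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average") # top gene ~ rank N
    ord <- order(-r, genes) # descending expression, ties by id
    rv <- r[ord]
    for (si in seq_along(sets)) {
      if (empty[si]) next
      m <- member[[si]][ord]
      w <- rv^alpha * m
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!m) / sum(!m)
      scores[j, si] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  class(scores) <- c("ssgsea_scores", class(scores))
  scores
}

#' Contrast infiltration scores between case and control samples
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity corrections) per cell type; the direction is the sign of the
#' case-minus-control median difference.
#'
#' @param scores Sample x cell-type matrix from [ssgsea()].
#' @param groups Character per sample (`case`/`control`), or a phenotype
#'   tibble with `sample` and `group`.
#' @return A tibble with `cell_type`, `w`, `p`, `direction`, `significant`.
#' @export
compare_infiltration <- function(scores, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample)[rownames(scores)]
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(scores)) {
    abort("`groups` must supply one label per sample")
  }
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    abort("both groups need at least 2 samples")
  }
  purrr::map_dfr(colnames(scores), function(ct) {
    x <- scores[groups == "case", ct]
    y <- scores[groups == "control", ct]
    if (all(is.na(x)) || all(is.na(y))) {
      return(tibble(
        cell_type = ct, w = NA_real_, p = NA_real_,
        direction = NA_character_, significant = NA
      ))
    }
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    md <- median(x, na.rm = TRUE) - median(y, na.rm = TRUE)
    tibble(
      cell_type = ct,
      w = unname(ht$statistic),
      p = ht$p.value,
      direction = if (md >= 0) "up" else "down",
      significant = ht$p.value < 0.05
    )
  })
}

#' Correlate hub-gene expression with immune-cell scores
#'
#' Spearman correlation (Pearson on ranks) with a t-approximation p-value
#' on `n - 2` df. A pair is flagged when `rho > cor_min` (signed; set
#' `signed = FALSE` to flag on `|rho|`) and `p < alpha`.
#'
#' @param expr Hub-gene x sample expression submatrix.
#' @param scores Sample x cell-type matrix from [ssgsea()] (same samples).
#' @param cor_min Correlation threshold (default 0.3, strict).
#' @param alpha P-value threshold (default 0.05, strict).
#' @param signed Flag positive correlations only (default TRUE).
#' @return A tibble with `gene_id`, `cell_type`, `rho`, `p`, `flagged`.
#' @export
correlate_genes_cells <- function(expr, scores, cor_min = 0.3, alpha = 0.05,
                                  signed = TRUE) {
  check_expr(expr, "expr")
  if (!identical(colnames(expr), rownames(scores))) {
    scores <- scores[colnames(expr), , drop = FALSE]
  }
  n <- ncol(expr)
  if (n < 4) abort("need at least 4 samples for correlation")
  out <- tidyr::expand_grid(
    gene_id = rownames(expr),
    cell_type = colnames(scores)
  )
  stats <- purrr::map2_dfr(out$gene_id, out$cell_type, function(g, ct) {
    y <- scores[, ct]
    if (all(is.na(y))) {
      return(tibble(rho = NA_real_, p = NA_real_))
    }
    rho <- cor(rank(expr[g, ]), rank(y))
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    tibble(rho = rho, p = 2 * pt(-abs(tt), df = n - 2))
  })
  out <- dplyr::bind_cols(out, stats)
  crit <- if (signed) out$rho > cor_min else abs(out$rho) > cor_min
  out$flagged <- crit & out$p < alpha
  out
}
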