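# Independent brute-force oracles used to validate the fast implementations.

# O(n^3) topological overlap by direct triple loop over the formula.
brute_tom <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- 1
  k <- rowSums(adj) - 1
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- adj[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + adj[i, u] * adj[u, j]
      }
      out[i, j] <- num / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  out
}

# Exhaustive maximal-clique MCC: check every vertex subset for clique-ness
# and maximality against the adjacency matrix (n <= 12).
brute_mcc <- function(am) {
  n <- nrow(am)
  score <- setNames(numeric(n), rownames(am))
  for (size in 2:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      sub <- am[idx, idx, drop = FALSE]
      if (any(sub[upper.tri(sub)] == 0)) next
      outside <- setdiff(seq_len(n), idx)
      maximal <- !any(vapply(outside, function(v) all(am[v, idx] == 1), TRUE))
      if (maximal) {
        score[idx] <- score[idx] + factorial(size - 1)
      }
    }
  }
  score
}

# Upper-tail hypergeometric probability by direct pmf summation.
brute_hyper_upper <- function(k, K, n, N) {
  if (K == 0) {
    return(1)
  }
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Naive weighted KS running-sum extremum over the full ranking.
brute_gsea_es <- function(ranked, set, weight = 1) {
  ranked <- sort(ranked, decreasing = TRUE)
  hits <- names(ranked) %in% set
  w <- abs(ranked)^weight
  inc <- numeric(length(ranked))
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / sum(!hits)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- sa * sb / np
  (sij - expected) / ((sa + sb) / 2 - expected)
}
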