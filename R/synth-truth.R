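# The 28 immune-cell signature names scored by the single-sample
# enrichment stage (the standard pan-immune cell-type panel).
IMMUNE_CELL_TYPES <- c(
  "Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
  "Activated dendritic cell", "CD56bright natural killer cell",
  "CD56dim natural killer cell", "Central memory CD4 T cell",
  "Central memory CD8 T cell", "Effector memory CD4 T cell",
  "Effector memory CD8 T cell", "Eosinophil", "Gamma delta T cell",
  "Immature B cell", "Immature dendritic cell", "Macrophage", "Mast cell",
  "MDSC", "Memory B cell", "Monocyte", "Natural killer cell",
  "Natural killer T cell", "Neutrophil", "Plasmacytoid dendritic cell",
  "Regulatory T cell", "T follicular helper cell", "Type 1 T helper cell",
  "Type 17 T helper cell", "Type 2 T helper cell"
)

#' Planted ground truth for a synthetic two-disease study
#'
#' Deterministically derives, from a [synth_config()], every planted fact the
#' downstream recovery tests score against: hub genes, module memberships,
#' per-disease differential-expression directions, the planted immune
#' signature, disease-association scores (with threshold-straddling decoys),
#' and the shared miRNAs with their hub targets.
#'
#' By construction the planted hubs are members of module 1, carry an
#' upregulated direction in disease A, and appear above both association
#' filter thresholds (relevance >= 10, PMID count >= 1) in the disease-B
#' tables.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_truth`.
#' @export
synth_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, "truth"), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))

    module <- integer(config$n_genes)
    idx <- 1L
    for (m in seq_len(config$n_modules)) {
      module[idx:(idx + config$module_sizes[m] - 1L)] <- m
      idx <- idx + config$module_sizes[m]
    }
    names(module) <- genes

    hubs <- genes[seq_len(config$n_planted_hubs)]
    background <- genes[module == 0L]

    # disease A: the whole of module 1 is upregulated (hubs included);
    # extra background DE genes exercise the intersection logic.
    n_bg <- min(config$n_background_de, length(background))
    bg_de <- if (n_bg > 0) sample(background, n_bg) else character()
    n_up <- ceiling(n_bg / 2)
    de_a <- setNames(rep("null", config$n_genes), genes)
    de_a[module == 1L] <- "up"
    de_a[bg_de[seq_len(n_up)]] <- "up"
    if (n_bg > n_up) de_a[bg_de[(n_up + 1L):n_bg]] <- "down"

    # disease B: the planted immune signature genes shift up in cases.
    sig_pool <- setdiff(background, bg_de)
    sig_genes <- sort(sample(sig_pool, min(config$immune_set_size, length(sig_pool))))
    sig_name <- sample(IMMUNE_CELL_TYPES, 1)
    de_b <- setNames(rep("null", config$n_genes), genes)
    de_b[sig_genes] <- "up"

    baseline <- setNames(runif(config$n_genes, 4, 10), genes)

    association <- synth_association_scores(genes, hubs, sig_genes, config)

    mirna <- synth_mirna_truth(genes, hubs, config)

    structure(
      list(
        genes = genes,
        planted_hubs = hubs,
        module_membership = module,
        de_direction = list(a = de_a, b = de_b),
        immune_signature = list(name = sig_name, genes = sig_genes),
        baseline = baseline,
        association = association$table,
        decoys = association$decoys,
        mirna_lists = mirna$lists,
        mirna_targets = mirna$targets,
        config = config
      ),
      class = "synth_truth"
    )
  })
}

# Association scores for the two disease-B sources. One row per
# (gene, source); relevance populated only for the relevance source and
# pmid_count only for the curation source.
synth_association_scores <- function(genes, hubs, sig_genes, config) {
  n <- config$n_assoc_genes
  n_decoy <- config$n_decoys
  pool <- setdiff(genes, hubs)
  decoy_genes <- sample(pool, n_decoy)
  # three decoy flavours, all of which must be rejected downstream
  kind <- rep(c("low_relevance", "zero_pmid", "single_source"), length.out = n_decoy)

  filler_pool <- setdiff(pool, decoy_genes)
  n_filler <- n - length(hubs) - n_decoy
  stopifnot(n_filler >= 0)
  filler <- sample(filler_pool, n_filler)

  rel_genes <- c(hubs, decoy_genes[kind != "single_source"], filler)
  rel <- tibble(
    gene_id = rel_genes,
    source = "relevance_source",
    relevance = runif(length(rel_genes), 0, 30),
    pmid_count = NA_integer_
  )
  rel$relevance[rel$gene_id %in% hubs] <- runif(length(hubs), 10, 50)
  low <- decoy_genes[kind == "low_relevance"]
  rel$relevance[match(low, rel$gene_id)] <- runif(length(low), 5, 9.9)
  zp <- decoy_genes[kind == "zero_pmid"]
  rel$relevance[match(zp, rel$gene_id)] <- runif(length(zp), 10, 20)
  # top up to exactly n rows with repeats of filler? keep exact count
  if (nrow(rel) < n) {
    extra <- sample(setdiff(filler_pool, filler), n - nrow(rel))
    rel <- bind_rows(rel, tibble(
      gene_id = extra, source = "relevance_source",
      relevance = runif(length(extra), 0, 30), pmid_count = NA_integer_
    ))
  }

  cur_genes <- c(hubs, decoy_genes[kind != "single_source"], filler)
  cur <- tibble(
    gene_id = cur_genes,
    source = "curation_source",
    relevance = NA_real_,
    pmid_count = rbinom(length(cur_genes), 10, 0.3)
  )
  cur$pmid_count[cur$gene_id %in% hubs] <- 1L + rbinom(length(hubs), 20, 0.3)
  cur$pmid_count[match(zp, cur$gene_id)] <- 0L
  cur$pmid_count[match(low, cur$gene_id)] <- 1L + rbinom(length(low), 10, 0.3)
  ss <- decoy_genes[kind == "single_source"]
  # single-source decoys: strong values but present in only one table
  cur <- bind_rows(cur, tibble(
    gene_id = ss, source = "curation_source",
    relevance = NA_real_, pmid_count = 1L + rbinom(length(ss), 10, 0.5)
  ))
  if (nrow(cur) > n) cur <- cur[seq_len(n), , drop = FALSE]
  if (nrow(cur) < n) {
    extra <- sample(setdiff(filler_pool, c(filler, ss)), n - nrow(cur))
    cur <- bind_rows(cur, tibble(
      gene_id = extra, source = "curation_source",
      relevance = NA_real_, pmid_count = rbinom(length(extra), 10, 0.3)
    ))
  }

  list(
    table = bind_rows(rel, cur),
    decoys = tibble(gene_id = decoy_genes, reason = kind)
  )
}

synth_mirna_truth <- function(genes, hubs, config) {
  total <- config$n_mirnas_a + config$n_mirnas_b - config$n_shared_mirnas
  ids <- sprintf("hsa-mir-%d-5p", sample(10:5000, total))
  shared <- ids[seq_len(config$n_shared_mirnas)]
  only_a <- ids[config$n_shared_mirnas + seq_len(config$n_mirnas_a - config$n_shared_mirnas)]
  only_b <- setdiff(ids, c(shared, only_a))

  targets <- lapply(setNames(ids, ids), function(m) {
    tg <- sample(genes, config$targets_per_mirna)
    if (m %in% shared && !any(tg %in% hubs)) {
      tg[1] <- sample(hubs, 1) # every shared miRNA hits >= 1 planted hub
    }
    sort(unique(tg))
  })

  list(
    lists = list(a = sort(c(shared, only_a)), b = sort(c(shared, only_b)), shared = sort(shared)),
    targets = targets
  )
}
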