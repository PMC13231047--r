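#' Pipeline configuration with the published thresholds as defaults
#'
#' Collects every tunable threshold of every stage, with the conventional
#' printed defaults: `|log2FC| > 1` and adjusted p `< 0.05` for DEGs, top
#' 5000 MAD genes, scale-free R^2 `> 0.85`, minimum interaction score 0.4,
#' MCODE (degree cutoff 2, k-core 2, node score cutoff 0.2, haircut on,
#' fluff off), MCC top 20, relevance `>= 10`, PMIDs `> 0`, enrichment
#' adjusted p `< 0.05`, `|NES| > 1`, correlation `> 0.3`, and a 30-day
#' minimum follow-up. All values can be overridden.
#'
#' @param input_dir Directory holding the pipeline inputs (see
#'   [simulate_inputs()] for the expected layout).
#' @param out_dir Directory for stage outputs (created if absent).
#' @param ... Overrides for any default listed above; unknown names error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    out_dir = out_dir,
    lfc = 1,
    alpha = 0.05,
    log_transform = FALSE,
    quantile_normalize = FALSE,
    mad_top = 5000,
    powers = 1:20,
    r2_min = 0.85,
    min_module_size = 30,
    cut_height = 0.99,
    relevance_min = 10,
    pmid_min = 1,
    min_score = 0.4,
    mcode_degree_cutoff = 2,
    mcode_k_core = 2,
    mcode_node_score_cutoff = 0.2,
    mcode_haircut = TRUE,
    mcode_fluff = FALSE,
    mcc_top = 20,
    ora_alpha = 0.05,
    top_terms = 20,
    gsea_n_perm = 1000,
    nes_min = 1,
    ssgsea_alpha = 0.25,
    cor_min = 0.3,
    followup_min = 30,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown pipeline option(s): %s", paste(unknown, collapse = ", ")),
      class = "comorbhub_config_error"
    )
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with at least `input_dir` and `out_dir`; other
#'   keys override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$out_dir)) {
    abort("YAML config must set input_dir and out_dir", class = "comorbhub_config_error")
  }
  do.call(pipeline_config, y)
}

#' Write a complete, immediately runnable synthetic input bundle
#'
#' Generates every pipeline input from a [synth_config()] and writes it to
#' `dir`: four expression/phenotype cohort TSVs, the scored interaction
#' edge table, the disease-B association tables, the survival table
#' (disease-A cohort 1 case samples), the two miRNA disease lists and
#' target map, the pathway and immune-signature GMT collections, and the
#' planted truth as JSON.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the `truth` and the file `manifest`.
#' @export
simulate_inputs <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(config)
  truth <- sim$truth
  for (id in names(sim$cohorts)) {
    write_expression(sim$cohorts[[id]]$expr, file.path(dir, sprintf("expr_%s.tsv", id)))
    write_phenotype(sim$cohorts[[id]]$pheno, file.path(dir, sprintf("pheno_%s.tsv", id)))
  }
  write_edge_table(generate_ppi(truth, config), file.path(dir, "ppi.tsv"))
  readr::write_tsv(generate_disease_associations(truth, config),
    file.path(dir, "associations_b.tsv"),
    progress = FALSE
  )
  case_a1 <- sim$cohorts$a1$pheno$sample[sim$cohorts$a1$pheno$group == "case"]
  surv <- generate_survival(sim$cohorts$a1$expr[, case_a1, drop = FALSE], truth, config)
  readr::write_tsv(surv, file.path(dir, "survival.tsv"), progress = FALSE)
  mir <- generate_mirna_maps(truth, config)
  writeLines(mir$list_a, file.path(dir, "mirna_disease_a.txt"))
  writeLines(mir$list_b, file.path(dir, "mirna_disease_b.txt"))
  readr::write_tsv(mir$target_map, file.path(dir, "mirna_targets.tsv"), progress = FALSE)
  sig <- generate_signatures(truth, config)
  write_gmt(sig$immune, file.path(dir, "immune_signatures.gmt"))
  write_gmt(sig$pathways, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(
    list(
      planted_hubs = truth$planted_hubs,
      module_membership = as.list(truth$module_membership),
      de_direction = lapply(truth$de_direction, as.list),
      immune_signature = truth$immune_signature,
      decoys = truth$decoys,
      shared_mirnas = truth$mirna_lists$shared,
      mirna_targets = truth$mirna_targets
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, dataframe = "rows"
  )
  manifest <- file_manifest(dir)
  invisible(list(truth = truth, manifest = manifest))
}

file_manifest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  tibble(
    file = sub(paste0("^", dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
}

stage_fail <- function(stage, parent) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
    class = "comorbhub_stage_error", parent = parent
  )
}

read_cohort <- function(cfg, id) {
  expr_path <- file.path(cfg$input_dir, sprintf("expr_%s.tsv", id))
  pheno_path <- file.path(cfg$input_dir, sprintf("pheno_%s.tsv", id))
  if (!file.exists(expr_path)) abort(sprintf("missing input file %s", expr_path))
  if (!file.exists(pheno_path)) abort(sprintf("missing input file %s", pheno_path))
  expr <- preprocess_expression(read_expression(expr_path),
    log_transform = cfg$log_transform,
    quantile_normalize = cfg$quantile_normalize
  )
  list(expr = expr, pheno = read_phenotype(pheno_path))
}

#' Run the full comorbidity hub-gene pipeline
#'
#' Executes, in order: differential expression (moderated and unmoderated
#' configurations on both disease-A cohorts, with direction-consistent
#' intersection), co-expression module detection on both cohorts, the
#' three-step disease-A gene set and the dual-source disease-B filter,
#' common hub genes, per-disease network analysis (centrality pre-filter,
#' MCODE, MCC, triangulation) and key hub genes, enrichment (ORA on both
#' gene sets, shared top terms, per-hub median-split GSEA), immune
#' infiltration scoring and hub-gene correlations, median-split survival
#' for the common hubs, and the miRNA-mRNA regulatory network. Each
#' stage's outputs are written under `out_dir` before the next stage runs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report` (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())

  de <- tryCatch(stage_de(config), error = function(e) stage_fail("de", e))
  report$stages$de <- de$summary

  wg <- tryCatch(stage_wgcna(config), error = function(e) stage_fail("wgcna", e))
  report$stages$wgcna <- wg$summary

  sets <- tryCatch(stage_sets(config, de, wg), error = function(e) stage_fail("sets", e))
  report$stages$sets <- sets$summary

  hubs <- tryCatch(stage_hubs(config, sets), error = function(e) stage_fail("hubs", e))
  report$stages$hubs <- hubs$summary

  enr <- tryCatch(stage_enrich(config, sets), error = function(e) stage_fail("enrich", e))
  report$stages$enrich <- enr$summary

  imm <- tryCatch(stage_immune(config, sets), error = function(e) stage_fail("immune", e))
  report$stages$immune <- imm$summary

  sv <- tryCatch(stage_survival(config, sets), error = function(e) stage_fail("survival", e))
  report$stages$survival <- sv$summary

  mir <- tryCatch(stage_mirna(config, sets), error = function(e) stage_fail("mirna", e))
  report$stages$mirna <- mir$summary

  report$disease_a_genes <- sets$disease_a$genes
  report$disease_b_genes <- sets$disease_b
  report$common_hub_genes <- sets$common
  report$key_hub_genes <- hubs$key_hub_genes
  report$manifest <- file_manifest(config$out_dir)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, dataframe = "rows", digits = NA
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d disease-A genes, %d disease-B genes, %d common hubs, %d key hubs\n",
    length(x$disease_a_genes), length(x$disease_b_genes),
    length(x$common_hub_genes), length(x$key_hub_genes)
  ))
  invisible(x)
}

stage_de <- function(cfg) {
  fits <- list()
  for (id in c("a1", "a2")) {
    co <- read_cohort(cfg, id)
    for (mod in c("eb", "none")) {
      fit <- fit_de(co$expr, co$pheno, moderation = mod)
      fits[[paste(id, mod, sep = "_")]] <- fit
      write_de_table(fit, file.path(cfg$out_dir, sprintf("de_%s_%s.tsv", id, mod)))
    }
  }
  degs <- lapply(fits, classify_degs, lfc = cfg$lfc, alpha = cfg$alpha)
  consistent_eb <- intersect_consistent(degs$a1_eb, degs$a2_eb)
  consistent_none <- intersect_consistent(degs$a1_none, degs$a2_none)
  list(
    fits = fits, degs = degs,
    consistent_eb = consistent_eb, consistent_none = consistent_none,
    summary = list(
      n_deg = lapply(degs, function(d) lengths(d)),
      n_consistent = lengths(consistent_eb)
    )
  )
}

stage_wgcna <- function(cfg) {
  res <- list()
  for (id in c("a1", "a2")) {
    co <- read_cohort(cfg, id)
    trait <- setNames(as.numeric(co$pheno$group == "case"), co$pheno$sample)
    fit <- run_coexpression(co$expr, trait,
      mad_top = cfg$mad_top, powers = cfg$powers, r2_min = cfg$r2_min,
      min_module_size = cfg$min_module_size, cut_height = cfg$cut_height
    )
    readr::write_tsv(fit$outliers, file.path(cfg$out_dir, sprintf("outliers_%s.tsv", id)), progress = FALSE)
    readr::write_tsv(fit$scan$scan, file.path(cfg$out_dir, sprintf("soft_threshold_%s.tsv", id)), progress = FALSE)
    readr::write_tsv(fit$assignment, file.path(cfg$out_dir, sprintf("modules_%s.tsv", id)), progress = FALSE)
    readr::write_tsv(fit$module_trait$table, file.path(cfg$out_dir, sprintf("module_trait_%s.tsv", id)), progress = FALSE)
    res[[id]] <- fit
  }
  list(
    fits = res,
    summary = lapply(res, function(f) {
      list(
        excluded_samples = f$outliers$sample[f$outliers$excluded],
        chosen_beta = f$scan$chosen_beta,
        n_modules = length(setdiff(unique(f$assignment$module), 0L)),
        strongest_module_size = length(f$strongest_module_genes)
      )
    })
  )
}

stage_sets <- function(cfg, de, wg) {
  a_set <- derive_disease_a(
    de$consistent_eb, de$consistent_none,
    wg$fits$a1$strongest_module_genes, wg$fits$a2$strongest_module_genes
  )
  assoc_path <- file.path(cfg$input_dir, "associations_b.tsv")
  if (!file.exists(assoc_path)) abort(sprintf("missing input file %s", assoc_path))
  assoc <- readr::read_tsv(assoc_path, show_col_types = FALSE, progress = FALSE)
  b_set <- filter_disease_b(assoc,
    relevance_min = cfg$relevance_min, pmid_min = cfg$pmid_min
  )
  common <- common_hubs(a_set$genes, b_set)
  write_gene_set(a_set, file.path(cfg$out_dir, "disease_a_genes"))
  write_gene_list(b_set, file.path(cfg$out_dir, "disease_b_genes.txt"))
  write_gene_list(common, file.path(cfg$out_dir, "common_hub_genes.txt"))
  list(
    disease_a = a_set, disease_b = b_set, common = common,
    summary = list(
      n_disease_a = length(a_set$genes),
      n_disease_b = length(b_set),
      n_common = length(common)
    )
  )
}

stage_hubs <- function(cfg, sets) {
  ppi_path <- file.path(cfg$input_dir, "ppi.tsv")
  if (!file.exists(ppi_path)) abort(sprintf("missing input file %s", ppi_path))
  full <- load_network(ppi_path, min_score = cfg$min_score)
  per_disease <- list()
  for (d in c("a", "b")) {
    genes <- if (d == "a") sets$disease_a$genes else sets$disease_b
    keep <- intersect(igraph::V(full)$name, genes)
    net <- igraph::induced_subgraph(full, keep)
    net <- igraph::delete_vertices(net, which(igraph::degree(net) == 0))
    if (igraph::vcount(net) < 3) {
      warn(sprintf("disease-%s network too small after filtering; no key hubs", d))
      per_disease[[d]] <- list(key = character(), n = igraph::vcount(net))
      next
    }
    cent <- centralities(net)
    clusters <- mcode(net,
      degree_cutoff = cfg$mcode_degree_cutoff, k_core = cfg$mcode_k_core,
      node_score_cutoff = cfg$mcode_node_score_cutoff,
      haircut = cfg$mcode_haircut, fluff = cfg$mcode_fluff
    )
    ranking <- mcc(net, top_n = cfg$mcc_top)
    key <- triangulate_hubs(cent, clusters, ranking)
    readr::write_tsv(cent, file.path(cfg$out_dir, sprintf("centrality_%s.tsv", d)), progress = FALSE)
    readr::write_tsv(
      tidyr::unnest(
        dplyr::select(clusters, "cluster", "score", "members"),
        "members"
      ),
      file.path(cfg$out_dir, sprintf("mcode_%s.tsv", d)),
      progress = FALSE
    )
    readr::write_tsv(ranking, file.path(cfg$out_dir, sprintf("mcc_%s.tsv", d)), progress = FALSE)
    write_graphml(net, file.path(cfg$out_dir, sprintf("network_%s.graphml", d)))
    per_disease[[d]] <- list(
      key = key, n = igraph::vcount(net), m = igraph::ecount(net),
      top_score = if (nrow(clusters)) clusters$score[1] else NA_real_
    )
  }
  key_hubs <- sorted_unique(intersect(per_disease$a$key, per_disease$b$key))
  write_gene_list(key_hubs, file.path(cfg$out_dir, "key_hub_genes.txt"))
  list(
    per_disease = per_disease, key_hub_genes = key_hubs,
    summary = list(
      network_sizes = lapply(per_disease, function(x) x[c("n", "m")]),
      n_key_per_disease = lapply(per_disease, function(x) length(x$key)),
      n_key = length(key_hubs)
    )
  )
}

stage_enrich <- function(cfg, sets) {
  gmt_path <- file.path(cfg$input_dir, "pathways.gmt")
  if (!file.exists(gmt_path)) abort(sprintf("missing input file %s", gmt_path))
  pathways <- read_gmt(gmt_path)
  co <- read_cohort(cfg, "a1")
  universe <- rownames(co$expr)

  res_a <- ora(sets$disease_a$genes, pathways, universe)
  res_b <- ora(intersect(sets$disease_b, universe), pathways, universe)
  shared <- shared_terms(res_a, res_b, top_n = cfg$top_terms)
  readr::write_tsv(res_a, file.path(cfg$out_dir, "ora_disease_a.tsv"), progress = FALSE)
  readr::write_tsv(res_b, file.path(cfg$out_dir, "ora_disease_b.tsv"), progress = FALSE)
  write_gene_list(shared, file.path(cfg$out_dir, "shared_pathways.txt"))

  # per-hub median-split GSEA within disease-A cases
  case <- co$pheno$sample[co$pheno$group == "case"]
  gsea_rows <- list()
  for (hub in intersect(sets$common, universe)) {
    grp <- median_split(co$expr, hub, samples = case)
    labels <- ifelse(grp == "high", "case", "control")
    fit <- fit_de(co$expr[, case, drop = FALSE], labels, moderation = "none")
    ranked <- setNames(fit$table$t, fit$table$gene_id)
    ranked <- ranked[is.finite(ranked)]
    res <- gsea_collection(ranked, pathways,
      n_perm = cfg$gsea_n_perm,
      seed = child_seed(cfg$seed, paste0("gsea_", hub))
    )
    if (nrow(res)) gsea_rows[[hub]] <- mutate(res, gene_id = hub, .before = 1)
  }
  gsea_tab <- bind_rows(gsea_rows)
  if (nrow(gsea_tab)) {
    readr::write_tsv(gsea_tab, file.path(cfg$out_dir, "gsea_hub_genes.tsv"), progress = FALSE)
  }
  list(
    res_a = res_a, res_b = res_b, shared = shared, gsea = gsea_tab,
    summary = list(
      n_sig_a = sum(res_a$significant), n_sig_b = sum(res_b$significant),
      shared_terms = shared,
      n_gsea_sig = if (nrow(gsea_tab)) sum(gsea_tab$significant) else 0L
    )
  )
}

stage_immune <- function(cfg, sets) {
  gmt_path <- file.path(cfg$input_dir, "immune_signatures.gmt")
  if (!file.exists(gmt_path)) abort(sprintf("missing input file %s", gmt_path))
  immune <- read_gmt(gmt_path)
  out <- list()
  for (id in c("a1", "b1")) {
    co <- read_cohort(cfg, id)
    scores <- ssgsea(co$expr, immune, alpha = cfg$ssgsea_alpha)
    contrast <- compare_infiltration(scores, co$pheno)
    hubs <- intersect(sets$common, rownames(co$expr))
    cors <- if (length(hubs)) {
      correlate_genes_cells(co$expr[hubs, , drop = FALSE], scores,
        cor_min = cfg$cor_min, alpha = cfg$alpha
      )
    } else {
      NULL
    }
    readr::write_tsv(
      tibble::as_tibble(unclass(scores), rownames = "sample"),
      file.path(cfg$out_dir, sprintf("ssgsea_%s.tsv", id)),
      progress = FALSE
    )
    readr::write_tsv(contrast, file.path(cfg$out_dir, sprintf("infiltration_%s.tsv", id)), progress = FALSE)
    if (!is.null(cors)) {
      readr::write_tsv(cors, file.path(cfg$out_dir, sprintf("immune_correlation_%s.tsv", id)), progress = FALSE)
    }
    out[[id]] <- list(contrast = contrast, correlations = cors)
  }
  list(
    cohorts = out,
    summary = lapply(out, function(x) {
      list(
        n_sig_cell_types = sum(x$contrast$significant, na.rm = TRUE),
        n_flagged_pairs = if (is.null(x$correlations)) 0L else sum(x$correlations$flagged, na.rm = TRUE)
      )
    })
  )
}

stage_survival <- function(cfg, sets) {
  surv_path <- file.path(cfg$input_dir, "survival.tsv")
  if (!file.exists(surv_path)) abort(sprintf("missing input file %s", surv_path))
  records <- readr::read_tsv(surv_path, show_col_types = FALSE, progress = FALSE)
  co <- read_cohort(cfg, "a1")
  genes <- intersect(sets$common, rownames(co$expr))
  if (!length(genes)) {
    warn("no common hub genes with expression; survival stage skipped")
    return(list(panel = NULL, summary = list(n_genes = 0L)))
  }
  panel <- survival_panel(co$expr, records, genes = genes, min_days = cfg$followup_min)
  readr::write_tsv(panel$summary, file.path(cfg$out_dir, "survival_summary.tsv"), progress = FALSE)
  list(
    panel = panel,
    summary = list(
      n_genes = nrow(panel$summary),
      n_significant = sum(panel$summary$p < 0.05, na.rm = TRUE)
    )
  )
}

stage_mirna <- function(cfg, sets) {
  paths <- file.path(cfg$input_dir, c(
    "mirna_disease_a.txt", "mirna_disease_b.txt", "mirna_targets.tsv"
  ))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(sprintf("missing input file %s", missing[1]))
  list_a <- readLines(paths[1])
  list_b <- readLines(paths[2])
  target_map <- readr::read_tsv(paths[3], show_col_types = FALSE, progress = FALSE)
  shared <- shared_mirnas(list_a, list_b)
  edges <- hub_targets(shared, target_map, sets$common)
  net <- build_regulatory_network(shared, edges)
  export_network(net, file.path(cfg$out_dir, "mirna_network.sif"), "sif")
  export_network(net, file.path(cfg$out_dir, "mirna_network.graphml"), "graphml")
  list(
    shared = shared, edges = edges, network = net,
    summary = list(
      n_shared = length(shared),
      n_targeted_hubs = length(unique(edges$gene)),
      n_unconnected = length(attr(edges, "unconnected"))
    )
  )
}
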