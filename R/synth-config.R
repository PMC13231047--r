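#' Configuration for the synthetic two-disease study generator
#'
#' Builds and validates the configuration driving every synthetic-data
#' generator. The defaults emulate the structure of a two-disease
#' comorbidity study: two case/control expression cohorts per disease
#' (cohort sizes mirror typical discovery designs: 130/10 and 80/80 for
#' disease A, 24/62 and 12/12 for disease B), correlated gene modules
#' produced by a latent-factor Gaussian model, direction-consistent planted
#' differentially expressed genes, a planted set of shared hub genes that
#' pass both disease-association filters, survival times tied to hub
#' expression, and miRNA target maps that hit the planted hubs.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_case,n_control Named lists with elements `a` and `b`, each an
#'   integer vector of per-cohort case (control) sample counts.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of module sizes (length `n_modules`).
#' @param module_latent_cor Within-module latent correlation rho in `[0, 1]`.
#' @param n_planted_hubs Number of planted shared hub genes (members of
#'   module 1).
#' @param de_effect_log2 Log2 fold-change magnitude added to case samples of
#'   planted differentially expressed genes in disease A.
#' @param noise_sd Standard deviation of the stochastic part of expression
#'   (log2-like scale).
#' @param immune_effect_log2 Shift added to the planted immune-signature
#'   genes in disease-B case samples.
#' @param n_background_de Number of planted DE genes outside modules in
#'   disease A (half up, half down).
#' @param survival_hazard_log_hr Per-unit log hazard ratio for standardized
#'   mean planted-hub expression.
#' @param censor_rate Target censoring fraction in `[0, 1]`.
#' @param baseline_hazard Baseline exponential hazard per day.
#' @param ppi_within_module_p,ppi_background_p Edge probabilities for
#'   within-module and background protein-interaction pairs.
#' @param n_mirnas_a,n_mirnas_b,n_shared_mirnas miRNA list sizes and the
#'   number shared between the two disease lists.
#' @param targets_per_mirna Targets drawn per miRNA.
#' @param n_assoc_genes Rows per disease-association source table.
#' @param n_decoys Decoy genes whose association values straddle the filter
#'   thresholds.
#' @param immune_set_size Genes per immune-cell signature.
#' @param n_pathway_decoys Decoy pathway gene sets beside the per-module
#'   pathway sets.
#' @param seed Global integer seed; every generator derives a stable child
#'   seed from it.
#'
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 300, seed = 7)
#' cfg$module_sizes
synth_config <- function(n_genes = 1000,
                         n_case = list(a = c(130L, 80L), b = c(24L, 12L)),
                         n_control = list(a = c(10L, 80L), b = c(62L, 12L)),
                         n_modules = 2,
                         module_sizes = c(100L, 100L),
                         module_latent_cor = 0.8,
                         n_planted_hubs = 6,
                         de_effect_log2 = 2,
                         noise_sd = 0.5,
                         immune_effect_log2 = 1,
                         n_background_de = 50,
                         survival_hazard_log_hr = 1,
                         censor_rate = 0.3,
                         baseline_hazard = 1 / 500,
                         ppi_within_module_p = 0.3,
                         ppi_background_p = 0.002,
                         n_mirnas_a = 45,
                         n_mirnas_b = 60,
                         n_shared_mirnas = 12,
                         targets_per_mirna = 20,
                         n_assoc_genes = 300,
                         n_decoys = 20,
                         immune_set_size = 30,
                         n_pathway_decoys = 10,
                         seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_case = lapply(n_case, as.integer),
    n_control = lapply(n_control, as.integer),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    module_latent_cor = module_latent_cor,
    n_planted_hubs = as.integer(n_planted_hubs),
    de_effect_log2 = de_effect_log2,
    noise_sd = noise_sd,
    immune_effect_log2 = immune_effect_log2,
    n_background_de = as.integer(n_background_de),
    survival_hazard_log_hr = survival_hazard_log_hr,
    censor_rate = censor_rate,
    baseline_hazard = baseline_hazard,
    ppi_within_module_p = ppi_within_module_p,
    ppi_background_p = ppi_background_p,
    n_mirnas_a = as.integer(n_mirnas_a),
    n_mirnas_b = as.integer(n_mirnas_b),
    n_shared_mirnas = as.integer(n_shared_mirnas),
    targets_per_mirna = as.integer(targets_per_mirna),
    n_assoc_genes = as.integer(n_assoc_genes),
    n_decoys = as.integer(n_decoys),
    immune_set_size = as.integer(immune_set_size),
    n_pathway_decoys = as.integer(n_pathway_decoys),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(
    cfg$n_genes, cfg$n_modules, cfg$module_sizes, cfg$n_planted_hubs,
    unlist(cfg$n_case), unlist(cfg$n_control),
    cfg$n_mirnas_a, cfg$n_mirnas_b, cfg$n_shared_mirnas,
    cfg$targets_per_mirna, cfg$n_assoc_genes, cfg$immune_set_size
  )
  if (any(counts < 1L)) {
    abort("all counts in a synth_config must be >= 1", class = "comorbhub_config_error")
  }
  probs <- c(
    cfg$module_latent_cor, cfg$censor_rate,
    cfg$ppi_within_module_p, cfg$ppi_background_p
  )
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "comorbhub_config_error")
  }
  if (length(cfg$module_sizes) != cfg$n_modules) {
    abort("`module_sizes` must have length `n_modules`", class = "comorbhub_config_error")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort("sum(module_sizes) exceeds n_genes", class = "comorbhub_config_error")
  }
  if (cfg$n_planted_hubs > cfg$module_sizes[1]) {
    abort("n_planted_hubs exceeds the first module's size", class = "comorbhub_config_error")
  }
  if (cfg$n_shared_mirnas > min(cfg$n_mirnas_a, cfg$n_mirnas_b)) {
    abort("n_shared_mirnas exceeds a disease miRNA list size", class = "comorbhub_config_error")
  }
  if (cfg$n_assoc_genes > cfg$n_genes) {
    abort("n_assoc_genes exceeds n_genes", class = "comorbhub_config_error")
  }
  if (!identical(sort(names(cfg$n_case)), c("a", "b")) ||
      !identical(sort(names(cfg$n_control)), c("a", "b"))) {
    abort("`n_case`/`n_control` must be lists with elements `a` and `b`",
      class = "comorbhub_config_error"
    )
  }
  if (length(cfg$n_case$a) != length(cfg$n_control$a) ||
      length(cfg$n_case$b) != length(cfg$n_control$b)) {
    abort("case and control cohort vectors must have matching lengths",
      class = "comorbhub_config_error"
    )
  }
  invisible(cfg)
}
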