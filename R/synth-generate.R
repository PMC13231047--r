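#' Generate synthetic expression cohorts for two diseases
#'
#' Draws four case/control cohorts (two per disease) from a latent-factor
#' Gaussian block model. Each planted module `m` has a per-sample latent
#' factor `f_m ~ N(0, 1)`; a member gene's stochastic part is
#' `noise_sd * (sqrt(rho) * f_m + sqrt(1 - rho) * eps)` with
#' `rho = module_latent_cor` and `eps ~ N(0, 1)`, so the within-module
#' correlation equals `rho` exactly and the marginal SD equals `noise_sd`.
#' Background genes are independent noise around their baseline. Planted
#' disease-A DE genes add `+/- de_effect_log2` to case samples in both
#' disease-A cohorts; the planted immune-signature genes add
#' `immune_effect_log2` to disease-B case samples. Values sit on a
#' log2-like scale, so the pipeline's `log2(x + 1)` step can be left off.
#'
#' @param config A [synth_config()].
#' @return A list with `cohorts` (named list `a1`, `a2`, `b1`, `b2`, each
#'   holding an `expr` genes x samples matrix and a `pheno` tibble with
#'   columns `sample` and `group`) and `truth` (the [synth_truth()]).
#' @export
#' @examples
#' sim <- generate_expression(synth_config(n_genes = 120, seed = 1))
#' dim(sim$cohorts$a1$expr)
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- synth_truth(config)
  cohorts <- list()
  for (disease in c("a", "b")) {
    for (k in seq_along(config$n_case[[disease]])) {
      id <- paste0(disease, k)
      cohorts[[id]] <- with_seed(child_seed(config$seed, paste0("expr_", id)), {
        synth_cohort(
          truth, config,
          disease = disease,
          n_case = config$n_case[[disease]][k],
          n_control = config$n_control[[disease]][k],
          prefix = id
        )
      })
    }
  }
  list(cohorts = cohorts, truth = truth)
}

synth_cohort <- function(truth, config, disease, n_case, n_control, prefix) {
  n_s <- n_case + n_control
  genes <- truth$genes
  samples <- sprintf("%s_S%03d", prefix, seq_len(n_s))
  group <- c(rep("case", n_case), rep("control", n_control))

  rho <- config$module_latent_cor
  module <- truth$module_membership
  eps <- matrix(rnorm(length(genes) * n_s), length(genes), n_s)
  x <- matrix(truth$baseline, length(genes), n_s)
  for (m in seq_len(config$n_modules)) {
    f <- rnorm(n_s)
    in_m <- module == m
    x[in_m, ] <- x[in_m, ] + config$noise_sd *
      (sqrt(rho) * matrix(f, sum(in_m), n_s, byrow = TRUE) +
        sqrt(1 - rho) * eps[in_m, , drop = FALSE])
  }
  bg <- module == 0L
  x[bg, ] <- x[bg, ] + config$noise_sd * eps[bg, , drop = FALSE]

  dir <- truth$de_direction[[disease]]
  effect <- if (disease == "a") config$de_effect_log2 else config$immune_effect_log2
  is_case <- group == "case"
  x[dir == "up", is_case] <- x[dir == "up", is_case] + effect
  x[dir == "down", is_case] <- x[dir == "down", is_case] - effect

  dimnames(x) <- list(genes, samples)
  list(
    expr = x,
    pheno = tibble(sample = samples, group = group)
  )
}

#' Generate a scored protein-interaction edge table
#'
#' Within-module gene pairs receive an edge with probability
#' `ppi_within_module_p`, all other pairs with `ppi_background_p`. Each
#' planted hub is additionally wired to at least half of its module.
#' Combined scores for kept edges are drawn uniformly on the 400-1000
#' integer range used by scored interaction databases.
#'
#' @param truth A [synth_truth()].
#' @param config The matching [synth_config()].
#' @return A tibble with columns `node1`, `node2`, `combined_score`.
#' @export
generate_ppi <- function(truth, config) {
  with_seed(child_seed(config$seed, "ppi"), {
    genes <- truth$genes
    module <- truth$module_membership
    n <- length(genes)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[pairs[, 1]] == module[pairs[, 2]] &
      module[pairs[, 1]] != 0L
    p <- ifelse(same, config$ppi_within_module_p, config$ppi_background_p)
    keep <- runif(nrow(pairs)) < p

    # hub reinforcement: each planted hub connects to >= half its module
    extra_i <- integer()
    extra_j <- integer()
    for (h in truth$planted_hubs) {
      hi <- match(h, genes)
      members <- setdiff(which(module == module[hi]), hi)
      want <- ceiling(length(members) / 2)
      chosen <- sample(members, want)
      extra_i <- c(extra_i, pmin(hi, chosen))
      extra_j <- c(extra_j, pmax(hi, chosen))
    }
    idx_all <- rbind(
      pairs[keep, , drop = FALSE],
      cbind(extra_i, extra_j, deparse.level = 0)
    )
    idx_all <- unique(idx_all)
    tibble(
      node1 = genes[idx_all[, 1]],
      node2 = genes[idx_all[, 2]],
      combined_score = sample(400:1000, nrow(idx_all), replace = TRUE)
    )
  })
}

#' Materialize the disease-B association tables
#'
#' Returns the association rows recorded in the planted truth: one table per
#' source (`relevance_source`, mirroring a relevance-scored gene database,
#' and `curation_source`, mirroring a literature-curated database with PMID
#' counts). Planted hubs sit above both filter thresholds; decoys straddle
#' them.
#'
#' @inheritParams generate_ppi
#' @return A tibble with columns `gene_id`, `source`, `relevance`,
#'   `pmid_count`.
#' @export
generate_disease_associations <- function(truth, config) {
  truth$association
}

#' Generate survival records tied to planted-hub expression
#'
#' Event times are exponential with hazard
#' `h0 * exp(beta * z)`, where `z` is the standardized per-sample mean
#' expression of the planted hub genes and `beta = survival_hazard_log_hr`.
#' Censoring is an independent exponential with rate
#' `h0 * censor_rate / (1 - censor_rate)`, giving the configured censoring
#' fraction under the null.
#'
#' @param expr A genes x samples expression matrix containing the planted
#'   hub genes.
#' @inheritParams generate_ppi
#' @return A tibble with columns `sample`, `time_days`, `event`.
#' @export
generate_survival <- function(expr, truth, config) {
  check_expr(expr, "expr")
  with_seed(child_seed(config$seed, "survival"), {
    hubs <- intersect(truth$planted_hubs, rownames(expr))
    if (length(hubs) == 0) abort("no planted hub genes found in `expr`")
    z <- colMeans(expr[hubs, , drop = FALSE])
    z <- as.numeric(scale(z))
    h0 <- config$baseline_hazard
    rate <- h0 * exp(config$survival_hazard_log_hr * z)
    t_event <- rexp(ncol(expr), rate)
    if (config$censor_rate > 0) {
      c_rate <- h0 * config$censor_rate / (1 - config$censor_rate)
      t_cens <- rexp(ncol(expr), c_rate)
    } else {
      t_cens <- rep(Inf, ncol(expr))
    }
    tibble(
      sample = colnames(expr),
      time_days = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Materialize the per-disease miRNA lists and the miRNA-target map
#'
#' @inheritParams generate_ppi
#' @return A list with `list_a`, `list_b` (character vectors of miRNA ids)
#'   and `target_map` (a tibble with columns `mirna`, `target`). Every
#'   shared miRNA targets at least one planted hub by construction.
#' @export
generate_mirna_maps <- function(truth, config) {
  tm <- purrr::imap(truth$mirna_targets, function(tg, m) tibble(mirna = m, target = tg))
  list(
    list_a = truth$mirna_lists$a,
    list_b = truth$mirna_lists$b,
    target_map = bind_rows(tm)
  )
}

#' Generate pathway and immune-cell gene-set collections
#'
#' Builds two collections: `immune`, exactly 28 immune-cell signatures (one
#' of which is the planted signature recorded in the truth), and `pathways`,
#' one set per planted module plus decoy sets of random background genes.
#'
#' @inheritParams generate_ppi
#' @return A list of two gene-set collections, each a tibble with columns
#'   `set`, `description`, `genes` (list column), as returned by
#'   [read_gmt()].
#' @export
generate_signatures <- function(truth, config) {
  with_seed(child_seed(config$seed, "signatures"), {
    genes <- truth$genes
    sig_name <- truth$immune_signature$name
    others <- setdiff(IMMUNE_CELL_TYPES, sig_name)
    pool <- setdiff(genes, truth$immune_signature$genes)
    immune_sets <- c(
      setNames(list(truth$immune_signature$genes), sig_name),
      lapply(setNames(others, others), function(nm) {
        sort(sample(pool, config$immune_set_size))
      })
    )
    immune_sets <- immune_sets[IMMUNE_CELL_TYPES] # stable panel order
    immune <- tibble(
      set = names(immune_sets),
      description = "immune cell signature",
      genes = unname(immune_sets)
    )

    module <- truth$module_membership
    path_sets <- lapply(seq_len(config$n_modules), function(m) {
      sort(names(module)[module == m])
    })
    names(path_sets) <- sprintf("MODULE_PATHWAY_%d", seq_len(config$n_modules))
    bg <- names(module)[module == 0L]
    decoys <- lapply(seq_len(config$n_pathway_decoys), function(i) {
      sort(sample(bg, config$immune_set_size))
    })
    names(decoys) <- sprintf("DECOY_PATHWAY_%d", seq_len(config$n_pathway_decoys))
    all_sets <- c(path_sets, decoys)
    pathways <- tibble(
      set = names(all_sets),
      description = "synthetic pathway",
      genes = unname(all_sets)
    )
    list(immune = immune, pathways = pathways)
  })
}
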