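---
title: "Methods: comorbidity hub-gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity hub-gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbhub)
```

## The analysis

`comorbhub` implements a complete comorbidity hub-gene discovery pipeline
for two diseases studied through transcriptomics. Disease A is
characterized by case/control expression cohorts (two of them, to guard
against platform- and cohort-specific artifacts); disease B by curated
gene-association tables from two databases. The pipeline asks: which genes
are robustly tied to *both* conditions, how do they behave in interaction
networks, pathways, the immune microenvironment, and patient survival, and
which miRNAs could co-regulate them?

The stages, in order:

1. **Differential expression.** Per cohort, the case-minus-control log2
   fold change per gene with an empirical-Bayes moderated t-statistic, in
   two configurations (moderated and ordinary t). Genes are called up/down
   at the strict thresholds `|log2FC| > 1` and BH-adjusted `p < 0.05`, and
   only direction-consistent calls across cohorts survive.
2. **Weighted co-expression analysis.** Sample outliers are excluded at a
   strict `mu - 3*sigma` rule on mean inter-sample Pearson similarity; the
   top 5000 genes by median absolute deviation are kept; a soft-threshold
   power is scanned for approximate scale-free topology (`R^2 > 0.85`);
   the unsigned adjacency `|cor|^beta` is transformed to topological
   overlap; modules come from average-linkage clustering of `1 - TOM`; the
   module whose eigengene correlates most strongly (in absolute value)
   with case status contributes its genes.
3. **Disease gene sets.** Disease A: the three-step intersection
   (direction-consistent DEGs across cohorts, then across the two DE
   configurations, then with the shared strongest-module genes). Disease
   B: genes with relevance `>= 10` in the relevance-scored source *and*
   more than zero supporting PMIDs in the curated source. Common hub genes
   are their intersection.
4. **Network analysis.** A scored interaction network (combined score
   `>= 0.4` on the 0-1 scale, disconnected nodes hidden) is analysed per
   disease three ways: nodes above the network mean on degree,
   betweenness, and closeness simultaneously; MCODE molecular-complex
   detection (degree cutoff 2, k-core 2, node score cutoff 0.2, haircut
   on, fluff off) with clusters scored `density x n`; and maximal clique
   centrality (MCC), `sum over maximal cliques of (|C|-1)!`, top 20. Key
   hub genes are the triangulated intersection, then intersected across
   the diseases.
5. **Enrichment.** Hypergeometric over-representation of each disease set
   against a pathway collection (BH `< 0.05`), shared top-20 terms, and
   per-hub median-split GSEA with gene-set-permutation nulls
   (significant at adjusted `p < 0.05` and `|NES| > 1`).
6. **Immune infiltration.** Single-sample enrichment of 28 immune-cell
   signatures per sample (rank-based, exponent 0.25, min-max normalized),
   Wilcoxon rank-sum case/control contrasts, and Spearman correlations of
   hub-gene expression with cell scores (flagged at `rho > 0.3`,
   `p < 0.05`).
7. **Survival.** Median-split Kaplan-Meier curves with a log-rank test,
   after removing follow-up shorter than 30 days.
8. **Regulatory network.** The miRNAs shared by both disease lists, their
   curated targets restricted to the common hubs, and the typed
   disease-miRNA-gene network.

## The synthetic study generator

Real inputs of this kind come from repositories and curated databases.
`synth_config()` / `simulate_inputs()` generate a complete study with
planted ground truth so that every stage is verifiable offline:

- **Expression** follows a latent-factor Gaussian block model. Module `m`
  has a factor `f_m ~ N(0,1)` per sample; a member gene is
  `baseline + noise_sd * (sqrt(rho) f_m + sqrt(1-rho) eps)`, so the
  within-module correlation is exactly `rho` and the marginal SD is
  `noise_sd`. Values live on a log2-like scale; the pipeline's
  `log2(x+1)` step stays off for synthetic input.
- **Cohort sizes** default to 130/10 and 80/80 for disease A and 24/62
  and 12/12 for disease B — the shapes typical of discovery microarray
  or RNA-seq designs, where one cohort is heavily case-skewed.
- **Planted signal.** All of module 1 (including the `n_planted_hubs`
  hub genes) is upregulated by `de_effect_log2 = 2` in disease-A cases;
  extra background DEGs (half up, half down) exercise the intersection
  logic; the hubs additionally receive association scores above both
  disease-B thresholds while decoys straddle them (too-low relevance,
  zero PMIDs, or presence in a single source). One immune signature is
  shifted by `immune_effect_log2 = 1` in disease-B cases.
- **Interactions**: within-module pairs get edges with probability 0.3,
  background pairs 0.002, hubs are wired to at least half their module,
  and scores are uniform on 400-1000.
- **Survival** is exponential with hazard `h0 exp(beta z)` where `z` is
  the standardized mean planted-hub expression and `beta = 1` by default;
  censoring is an independent exponential with rate
  `h0 censor_rate / (1 - censor_rate)`, which attains the configured
  censoring fraction under the null (`beta = 0`) and approximately
  otherwise.
- **miRNAs**: 45 disease-A and 60 disease-B identifiers with exactly 12
  shared; every shared miRNA targets at least one planted hub.

One global seed fans out to stable per-generator child seeds, so adding a
generator never perturbs the others, and identical configurations produce
byte-identical input bundles.

What the generator does *not* emulate: platform-specific probe artifacts,
batch effects, library-size or count noise, gene-length effects,
correlated censoring, or miRNA identifier version drift. Tests passing on
this generator certify the algorithmic contracts — recovery of planted
structure under the stated noise model — not performance on any real
cohort.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lfc`, `alpha` | 1, 0.05 | DEG thresholds (strict inequalities) |
| `mad_top` | 5000 | variable genes kept for co-expression |
| `r2_min` | 0.85 | scale-free fit target for the power scan |
| `cut_height`, `min_module_size` | 0.99, 30 | static tree cut |
| `min_score` | 0.4 | interaction-score floor (0-1 scale, inclusive) |
| MCODE | 2/2/0.2/on/off | degree cutoff, k-core, node score cutoff, haircut, fluff |
| `mcc_top` | 20 | MCC nodes flagged (boundary ties all included) |
| `relevance_min`, `pmid_min` | 10, 1 | disease-B association filters |
| `nes_min`, `ora_alpha` | 1, 0.05 | enrichment significance |
| `cor_min` | 0.3 | signed Spearman flag threshold |
| `followup_min` | 30 | days of follow-up required |

All are recorded in `pipeline_config()` and overridable; the defaults are
the conventional published choices for this analysis family.

## Numerical and design choices

- **Variance moderation.** The prior `(d0, s0^2)` is estimated by
  moment-matching the distribution of `log s^2` through digamma/trigamma
  inversion (Newton iteration on the trigamma inverse). When the observed
  `log s^2` dispersion does not exceed `trigamma(d/2)` — no evidence of
  gene-specific variances — `d0` is set to infinity and `s0^2` to the
  geometric mean of the sample variances, which leaves exactly equal
  sample variances unshrunk. The ordinary-t configuration is the `d0 = 0`
  limit and doubles as the pipeline's second, platform-bias-checking DE
  route. The unit tests cross-check the moderated route against an
  independent reference implementation.
- **Soft-threshold fallback.** On data whose degree distribution is far
  from scale-free (including the block-model generator, which has two
  connectivity populations by design), no scanned power reaches
  `R^2 > 0.85` and the fit curve is essentially flat from the first
  power. A "first plateau" rule then degenerates to the smallest scanned
  power, which is too soft to separate modules under a static cut. The
  package instead falls back to the conventional sample-size-based
  default power for unsigned networks (9, 8, 7, 6 for under 20, 20-30,
  31-40, and more than 40 samples) and records a warning.
- **Static tree cut.** Modules come from a static cut (height 0.99,
  minimum size 30) rather than dynamic hybrid cutting: deterministic,
  easily testable, and sufficient for block-model recovery. A practical
  consequence on mixed data at soft powers: weakly correlated background
  genes can attach to module clusters below the cut. At the fallback
  powers chosen here the background detaches cleanly; on real data the
  dynamic cutter of the reference toolchain may split more finely.
- **Scale-free fit with equal-occupancy bins.** Connectivities are binned
  into 10 equal-occupancy bins; since counts per bin are then constant by
  construction, `p(k)` is estimated as a density (count / bin width) and
  the signed `R^2` of `log10 p(k)` on `log10 k` is reported, negated when
  the slope is positive.
- **MCODE reading.** The published parameters are attached to the staged
  algorithm of the original complex-detection method; the inclusion rule
  is `weight >= seed_weight * (1 - node_score_cutoff)`, the standard
  reading of "node score cutoff = 0.2". Fluff is not implemented (the
  printed setting is false). Haircut iterates to a fixed point.
- **MCC conventions.** Maximal cliques of size at least 2 are enumerated
  (pivoting Bron-Kerbosch); a node whose neighborhood has no internal
  edges receives its degree, which is what the `(|C|-1)!` sum yields on
  maximal 2-cliques. Ties at the rank-20 boundary are all retained (with
  a warning), so downstream triangulation cannot depend on enumeration
  order. An enumeration budget (default one million cliques) guards
  against pathological dense graphs.
- **GSEA null and p-value.** The null is gene-set permutation (same-size
  random sets), appropriate at desk scale where median splits leave few
  samples for phenotype permutation. `NES` divides the ES by the mean
  absolute same-sign null ES; the p-value is the smoothed same-sign
  exceedance `(1 + #{null >= |ES|}) / (1 + #same-sign null)`, which is
  uniform under the null (verified by a KS test in the suite) while
  bounding the smallest achievable p away from zero. The running-sum
  extremum is computed from hit positions only (O(set size) per
  permutation), verified against a full-scan oracle.
- **ssGSEA.** Genes are ranked per sample (average ranks on ties; the top
  gene carries rank value `N`), in-set genes weighted by `rank^0.25`, and
  the score is the summed difference between the weighted in-set ECDF and
  the uniform out-of-set ECDF, min-max normalized across the whole
  sample-by-set matrix. Scores therefore depend on expression only
  through ranks — the invariance the suite asserts under random monotone
  transforms.
- **ORA universe.** The universe defaults to the genes measured in the
  originating expression matrix; terms are truncated to the universe
  before testing.
- **Median-split ties** go to the low-expression group (configurable);
  relabeling the groups leaves the log-rank statistic unchanged.
- **Strongest module by `|cor|`.** Module-trait strength is judged on the
  absolute eigengene correlation, the safe generalization when
  interesting modules may anticorrelate with case status.
- **Gene identifiers** are exact strings; no alias or symbol-version
  resolution is attempted. miRNA identifiers are normalized only by
  lowercasing and trimming.

## Problem sizes used by the test suite

The default generator produces 1000 genes (two planted modules of 100)
and the four cohorts above; the end-to-end recovery property runs ten
seeded replicates of the full pipeline at those sizes. Calibration
properties use 2000 null replicates per test; survival power uses 50
replicates at 300 cases; immune-signature detection uses 20 replicates.
Brute-force oracles run at the largest sizes where exhaustive computation
is exact and fast (cliques up to 12 nodes, TOM up to 50 genes,
hypergeometric grids up to a 30-gene universe). These sizes are the
package's chosen verification scale; all thresholds are the analysis
defaults, not tuned per test.

## Known limitations

- The second DE configuration reproduces a web-based reanalysis route as
  the ordinary-t limit of the same fit; it is not an independent
  normalization pipeline.
- No dynamic tree cut, eigengene-based module merging, or block-wise
  decomposition for very large gene sets.
- No covariates or multi-factor designs in DE; overall survival is the
  only endpoint and no proportional-hazards model is fitted.
- Association-table and miRNA inputs are file-based snapshots; no live
  database access, evidence-grade filtering, or identifier harmonization.
- The key-hub triangulation can legitimately return an empty set on
  sparse networks (typical for the association-derived disease-B set at
  desk scale): all-three-routes agreement is a demanding criterion.
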