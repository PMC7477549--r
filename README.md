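# cytomap

Cytokines and their receptors are short-range immune messengers whose
expression is tightly tissue-restricted, and whose genetic regulation —
cis-eQTLs, GWAS associations, selection signals — is scattered across several
public resources. `cytomap` is an R package for analysts who want to
characterize a curated catalog of cytokine/chemokine (receptor) genes the way
an integrative expression–genetics study would: it quantifies
tissue-specificity of expression, summarizes the cis-eQTL landscape per gene,
classifies the direction of shared eQTL effects inside physical gene
clusters, measures eQTL tissue-sharing with Jaccard indexes, and integrates
GWAS-catalog associations with LD proxies, functional scores and
positive-selection statistics.

A curated catalog of 314 cytokine/chemokine (receptor) genes grouped by GO
activity class ships with the package
(`system.file("extdata", "cytokine_catalog.tsv", package = "cytomap")`).

## The statistics at the core

* **Tissue specificity.** For a gene with median expression
  `x_1, …, x_N` (TPM) across `N` tissues,

  * Tau = Σᵢ (1 − xᵢ/x_max) / (N − 1) — 0 for uniform expression, 1 for
    single-tissue expression;
  * TSI = x_max / Σᵢ xᵢ — ranges 1/N to 1.

  Genes are called tissue-specific when Tau ≥ 0.8 and additionally
  TSI ≥ 0.3 (both thresholds inclusive and configurable).

* **Effect direction.** Within a physical gene cluster, a SNP that is a
  significant eQTL for two member genes in the same tissue exerts a
  *unidirectional* effect when the two normalized effect sizes (NES) share a
  sign, *bidirectional* otherwise.

* **Tissue similarity.** Each tissue's eQTL signature is its set of
  (SNP, target gene, NES sign) triples; similarity between tissues is the
  Jaccard index 100·|A∩B|/|A∪B|.

* **GWAS integration.** Index SNPs are separated from LD proxies
  (r² > 0.8, population-matched), functional score distributions are
  compared by Kolmogorov–Smirnov, selection records are filtered on rank
  scores (−log10 centile, significant above 2), and measurement-trait
  enrichment among selection SNPs is tested with chi-square (Yates) or
  Fisher's exact test plus Benjamini–Hochberg FDR.

Every stage is fed either by TSV/GCT readers with full schema validation
(`read_table()`, `read_expression_gct()`) or by a seeded synthetic-data
generator (`sim_config()`, `gen_expression()`, `gen_eqtl()`, `gen_gwas()`)
that plants recoverable structure, so the whole pipeline is testable without
any database download.

## Worked example

```r
library(cytomap)

cfg    <- sim_config(seed = 1)          # study-scale defaults
gx     <- gen_expression(cfg)           # 300 genes x 54 tissues, median TPM
scores <- score_matrix(gx$matrix)
labels <- classify_specific(scores)     # Tau >= 0.8, TSI >= 0.3
mean(labels$label %in% c("specific_tau", "specific_tau_tsi")) * 100
#> [1] 82

catalog <- gen_catalog(cfg)
eq      <- gen_eqtl(cfg, catalog,
                    specific_genes = gx$truth$gene[gx$truth$is_specific])
tau_vs_esnps(scores, summarize_egenes(eq$eqtl, catalog))$rho
#> [1] -0.2953415

effects <- shared_effects(eq$eqtl, build_clusters(catalog))
summarize_pairs(effects)$global$bidirectional_fraction
#> [1] 0.3528084

jaccard_matrix(build_signatures(eq$eqtl))$mean_offdiag
#> [1] 8.991818
```

82% of the simulated genes are classified tissue-specific; the Spearman
correlation between Tau and per-gene eSNP counts is negative (tissue-specific
genes are regulated by fewer eQTLs); about 35% of shared cluster effects are
bidirectional; and mean cross-tissue Jaccard similarity of eQTL signatures is
low (~9 on the 0–100 scale), reflecting strong eQTL tissue-specificity.

The published selection/measurement association table is analyzed directly:

```r
measurement_enrichment(counts = matrix(c(348, 61, 1865, 789), 2, byrow = TRUE))
#> $prop_pct [1] 85.09 70.27   ... $p_value 6.875149e-10
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "cytomap.R", package = "cytomap")` with subcommands
`simulate`, `specificity`, `eqtl-summary`, `direction`, `jaccard` and
`gwas`.

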