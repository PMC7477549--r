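---
title: "Methods: tissue specificity, eQTL direction and GWAS integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue specificity, eQTL direction and GWAS integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomap)
```

`cytomap` characterizes a curated catalog of cytokine and cytokine-receptor
genes along three axes: how tissue-restricted their expression is, how their
expression is genetically regulated (significant cis-eQTLs), and how that
regulation connects to trait associations, LD structure and natural
selection. This vignette explains the models and procedures, the parameters
that matter, the synthetic-data generator used for validation, and the
numerical choices made where the design was open.

## Tissue-specificity metrics

For one gene with non-negative median expression values
$x_1, \dots, x_N$ (TPM) over $N \ge 2$ tissues,

$$\tau = \frac{\sum_{i=1}^{N} \left(1 - x_i / x_{\max}\right)}{N - 1},
\qquad
\mathrm{TSI} = \frac{x_{\max}}{\sum_{i=1}^{N} x_i},$$

with $x_{\max} = \max_i x_i$. Both are scale-invariant, increase as
expression concentrates into fewer tissues, and are undefined for an
all-zero profile. $\tau$ is 0 for a constant profile and 1 for
single-tissue expression; TSI ranges from $1/N$ (uniform) to 1.

Decisions worth stating explicitly:

* **Raw vs log scale.** The metrics are computed on raw median TPM by
  default, matching their original definitions. Because some analysts
  stabilize profiles first, `score_matrix(..., log2_offset = TRUE)`
  computes the metrics on $\log_2(x + 1)$; the log transform compresses
  dynamic range, so it systematically lowers $\tau$ and any count of
  $\tau \ge 0.8$ genes is sensitive to this flag.
* **Undetected genes** (all-zero profiles) are retained with `NA` scores
  and label `undefined` rather than dropped, so catalog bookkeeping
  reconciles exactly.
* **Classification thresholds** default to $\tau \ge 0.8$ and
  $\mathrm{TSI} \ge 0.3$, both inclusive. The TSI threshold is only applied
  on top of the $\tau$ threshold (`specific_tau_tsi` vs `specific_tau`).
* **Top-tissue ties** are broken by lexicographic tissue name and flagged,
  making outputs deterministic.
* **Tissue correlations** use Spearman rank correlation with midranks for
  ties; a constant tissue column yields undefined coefficients, which are
  flagged and excluded from the reported mean and range.

## eQTL landscape summaries

Inputs are pre-thresholded *significant* SNP–gene–tissue associations with
signed normalized effect sizes (NES); the package never estimates eQTLs
from genotypes, and q-value estimation is out of scope. Per catalog gene we
report the association count (SNP–tissue records), the distinct-eSNP count
and the distinct-tissue count; genes with no record are non-eGenes.
"Number of eQTLs per gene" is deliberately the *distinct SNP* count by
default — the association count is also emitted — because regulation
breadth is the quantity of interest and tissue replication would otherwise
double-count a SNP.

The specificity/regulation comparison excludes genes with undefined
$\tau$, reports group means ± SD, a Mann–Whitney rank-sum test (exact
below 50 per group, asymptotic with continuity correction otherwise — with
tied counts R's implementation falls back to the corrected normal
approximation) and a Kolmogorov–Smirnov test. An explicit `exclusions`
argument supports outlier-removal sensitivity analyses, with the honored
list echoed in the result.

## Direction of shared eQTL effects

Physical gene clusters are formed by single-linkage chaining: genes on one
chromosome join a cluster when the gap between consecutive genes (next
start minus running maximum end) is at most `max_gap_bp` (default 1 Mb, the
usual cis-window radius); singletons are dropped. When the catalog already
carries curated `cluster_id` assignments those take precedence, since
curated cluster definitions cannot be recovered from coordinates alone.

A *shared effect* is one (SNP, tissue, unordered gene pair) in which both
cluster members have a significant record for that SNP — matching is
strictly within tissue. Same-signed NES pairs are unidirectional,
opposite-signed bidirectional; with $k$ affected genes in one tissue all
$\binom{k}{2}$ pairs are emitted. Duplicate (SNP, tissue, gene) records
collapse to the smallest p-value before pairing.

Two reporting units exist in the literature — gene pairs and
pair–tissue–SNP associations — so `summarize_pairs()` emits both: per-pair
association tallies (`n_uni`, `n_bi`), contributing tissue counts, and
pair-level counts in the global statistics. "SNP distance" is defined here
as the mean pairwise genomic distance (kb) among the distinct SNPs
contributing to a pair's effects of a given direction class; a single
contributing SNP leaves it undefined. Mean LD is the average $r^2$ over all
unordered pairs of contributing SNPs found in the LD table, using the EUR
panel by default (LD lookups for other populations are selected with
`ld_population`); absent pairs are omitted and coverage is reported rather
than silently imputed.

## Jaccard tissue similarity

Each tissue's signature is the *set* of (SNP, target gene, NES sign)
triples among its records; a `match_on = "gene_sign"` switch relaxes the
match to (gene, sign) for sensitivity analyses. Similarity is
$J = 100\,|A \cap B| / |A \cup B|$, reported on the 0–100 scale (the raw
0–1 matrix is also returned). A pair of two empty signatures is defined as
$J = 0$ and flagged — keeping the matrix total rather than introducing
missing cells, consistent with a 0 lower bound. Gene and SNP filters
implement the three canonical analysis sets (catalog targets of GWAS
eSNPs; all targets of GWAS eSNPs; catalog targets genome-wide).

## GWAS integration

* **Index/LD partition.** LD proxies require $r^2$ *strictly* above the
  0.8 threshold and population matching within the four reference
  populations; mixed/unknown-population index SNPs contribute to index
  counts only. An LD SNP proxying several index SNPs counts once per
  population, and an index SNP is never simultaneously an LD SNP.
* **Contingency tests.** 2×2 tables use Pearson's chi-square with Yates's
  correction when every expected count is at least 5, Fisher's exact test
  otherwise (the conventional rule; the choice is reported). A zero row
  margin makes the test undefined (flagged); a zero column margin simply
  means no outcome variation and yields $p = 1$ through the exact test.
  FDR control is Benjamini–Hochberg.
* **Measurement enrichment** counts at the *association* level (one unit
  per association record), because per-SNP counting would hide trait
  multiplicity; an association is measurement-typed when its
  `measurement_type` category list is non-empty. A multi-gene
  `mapped_genes` entry counts once in association-level tallies (and once
  per gene in per-gene tallies elsewhere).
* **Selection filtering** retains records with rank score (−log10
  centile) strictly above 2. The conventional absolute cutoffs
  (Fst ≥ 0.5, |iHS| ≥ 2.0) are *reported per record but never enforced*:
  published absolute scores near the cutoff boundary make a hard filter on
  them unreliable, so conformance is surfaced for inspection instead.
* **Trait–tissue comparison** is a one-sided rank-sum test of whether a
  trait category's eQTL p-values are lower (more enriched) in one tissue
  category than another, FDR-adjusted across the tested pairs; cells with
  fewer than 3 records are skipped with a notice rather than tested at
  negligible power.

## The synthetic-data generator

All generators are pure functions of a `sim_config()`: child seeds are
derived deterministically from the master seed per generator, so any table
can be regenerated independently. Defaults encode the study conditions the
pipeline is meant to operate under:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `n_tissues` | 300, 54 | catalog-scale gene set; median-TPM tissue panel |
| `frac_specific` | 0.82 | planted fraction of tissue-specific genes |
| `specificity_strength` | 50 | top-tissue TPM over background mean |
| `baseline_tpm`, `expr_sdlog`, `gene_sdlog` | 5, 0.5, 1.0 | log-normal expression model (below) |
| `n_clusters`, `genes_per_cluster` | 10, 4 | planted physical clusters |
| `n_eqtl_snps` | 400 | shared cluster SNPs |
| `p_bidirectional` | 0.35 | opposite-sign probability per shared pair |
| `tissue_sharing` | 0.15 | per-tissue replication probability |
| `eqtl_rate_specific`, `eqtl_rate_other` | 4, 9 | background eSNPs per gene (plants the inverse Tau/eQTL dependence) |
| `populations` | 120/40/20/20/15/10 | EUR-dominated index SNP counts |
| `ld_frac_high` | 0.7 | fraction of LD partners above $r^2 = 0.8$ |
| `frac_selection` | 0.13 | planted selection-signal rate |
| `frac_selection_measurement`, `measurement_background` | 0.851, 0.703 | measurement-trait rates for selection vs other SNPs |

Model choices, and why:

* **Expression noise is multiplicative log-normal**, the simplest
  positive-valued model with a controllable $\tau$ distribution. Each gene
  draws a baseline level (log-normal, `gene_sdlog = 1`) shared across
  tissues, then independent per-tissue noise (`expr_sdlog = 0.5`). The
  shared baseline induces the strong positive inter-tissue rank
  correlation characteristic of median-TPM panels (mean Spearman ≈ 0.74 at
  the defaults) without touching the scale-invariant specificity metrics.
  At `expr_sdlog = 0.5` a non-specific 54-tissue profile exceeds
  $\tau = 0.8$ only rarely (~1.5%) and essentially never exceeds 0.95, so
  planted specificity is recoverable; at `specificity_strength = 50` a
  planted gene has $\tau \approx 0.98$ in expectation.
* **eQTL p-values are drawn only below the significance threshold**
  (`q_threshold`, default $10^{-4}$) since real inputs are pre-thresholded
  significant pairs; the density is $f(p) \propto p^{-1/2}$ on
  $(0, q]$ (i.e. $p = q\,U^2$), a simple decreasing density.
* **Shared cluster effects** assign each SNP one gene pair and one base
  tissue, flip the second sign with probability `p_bidirectional`, and
  replicate into each further tissue with probability `tissue_sharing`,
  preserving signs — so direction truth is defined per SNP and
  tissue-sharing is a separate, independently recoverable parameter.
* **Functional scores** are normal with an index-vs-LD mean shift of 2
  (SD 2): overlapping distributions, stochastically larger for index
  SNPs, matching the qualitative picture of aggregate functional scores.

What the generator does **not** emulate: realistic LD block structure
(pair lists are star-shaped around index SNPs), haplotypes or genotypes,
gene-length effects on eQTL counts, tissue sample-size imbalance, and the
EFO ontology graph (category lists are flat labels). Passing recovery
tests therefore demonstrates the pipeline's correctness and statistical
calibration on data with these planted properties — not that real GTEx- or
GWAS-derived tables satisfy the generator's assumptions.

## Problem sizes and numerical conventions

The validation suite works at deliberate desk scale: 300–2,000 genes,
54 tissues, up to ~2,000 shared eQTL SNPs, a few hundred index SNPs.
Parameter-recovery checks use 3-point grids per parameter and 3-standard-
error (binomial or Monte-Carlo) windows. Genome-scale record counts from
public databases are orders of magnitude larger and are covered by the
property-based suites and schema validation rather than regenerated.

Other conventions: coordinates are 1-based inclusive bp (GRCh38); gene
identity is by symbol; tabular outputs are written with a deterministic
column order and row sort so identical inputs give byte-identical files
(the manifest records an MD5 digest of the run configuration); unordered
LD pairs are canonicalized lexicographically at read time, with duplicates
rejected; all validation errors name the offending row.

## Known limitations

* Tissue-sharing and direction planting are independent per SNP; real
  eQTLs share across tissues in correlated blocks.
* The cluster chain rule is a 1 Mb single-linkage heuristic; curated
  cluster definitions, when available, should be supplied via
  `cluster_id`.
* `summarize_pairs()` treats LD coverage as missing-at-random when
  averaging $r^2$ over covered SNP pairs.
* The two-group rank-sum test switches between exact and asymptotic forms
  at $n = 50$; p-values near that boundary can shift slightly between the
  two regimes.
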