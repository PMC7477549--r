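# Per-gene eQTL summarization and specificity/regulation comparisons.

#' Summarize the eQTL landscape per catalog gene
#'
#' Counts, for every gene of the catalog, its SNP-tissue association
#' records, distinct eSNPs and distinct tissues. Catalog genes without any
#' association are retained as non-eGenes. eQTL records whose gene is not in
#' the catalog are dropped; their count is attached as attribute
#' `n_dropped`.
#'
#' @param eqtls data.frame in the `eqtl` schema.
#' @param catalog data.frame in the `gene_catalog` schema.
#' @return data.frame gene, n_associations, n_esnps, n_tissues, is_egene,
#'   with attribute `n_dropped`.
#' @export
summarize_egenes <- function(eqtls, catalog) {
  keep <- eqtls$gene %in% catalog$symbol
  n_dropped <- sum(!keep)
  eq <- eqtls[keep, , drop = FALSE]
  tab <- function(f) {
    v <- vapply(split(eq, eq$gene), f, numeric(1))
    unname(v[match(catalog$symbol, names(v))])
  }
  n_assoc <- tab(nrow)
  n_assoc[is.na(n_assoc)] <- 0
  n_esnps <- tab(function(d) length(unique(d$snp_id)))
  n_esnps[is.na(n_esnps)] <- 0
  n_tis <- tab(function(d) length(unique(d$tissue)))
  n_tis[is.na(n_tis)] <- 0
  out <- data.frame(gene = catalog$symbol,
                    n_associations = as.integer(n_assoc),
                    n_esnps = as.integer(n_esnps),
                    n_tissues = as.integer(n_tis),
                    is_egene = n_assoc > 0,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Rank correlation between Tau and per-gene eSNP counts
#'
#' Spearman correlation (with its two-sided p-value) between each gene's Tau
#' and the number of eSNPs regulating it. Genes with undefined Tau are
#' excluded (count attached as attribute `n_excluded`).
#'
#' @param scores data.frame from [score_matrix()].
#' @param summaries data.frame from [summarize_egenes()].
#' @param count Which count column to correlate against: `"n_esnps"`
#'   (distinct SNPs, default) or `"n_associations"`.
#' @return List with `rho`, `p_value`, `n`, and attribute-free bookkeeping
#'   field `n_excluded`.
#' @export
tau_vs_esnps <- function(scores, summaries, count = c("n_esnps",
                                                      "n_associations")) {
  count <- match.arg(count)
  m <- merge(scores[, c("gene", "tau")], summaries[, c("gene", count)],
             by = "gene")
  excl <- sum(is.na(m$tau))
  m <- m[!is.na(m$tau), , drop = FALSE]
  if (nrow(m) < 10L) analysis_error("need >= 10 genes with defined Tau")
  if (length(unique(m$tau)) == 1L || length(unique(m[[count]])) == 1L) {
    analysis_error("all-tied input: rank correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(m$tau, m[[count]],
                                         method = "spearman",
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
       n_excluded = excl)
}

#' Compare eQTL counts of tissue-specific versus other genes
#'
#' Two-group comparison of per-gene eQTL counts between genes classified
#' tissue-specific (`specific_tau_tsi`) and the remaining scored genes,
#' reporting group means +/- SD, a Mann-Whitney rank-sum p-value (exact for
#' group sizes below 50, asymptotic with continuity correction otherwise)
#' and a Kolmogorov-Smirnov p-value. Genes with undefined scores are
#' excluded; `exclusions` removes named genes (e.g. extreme outliers) before
#' testing, with the honored list recorded in the result.
#'
#' @param summaries data.frame from [summarize_egenes()].
#' @param labels data.frame from [classify_specific()].
#' @param exclusions Optional character vector of gene symbols to drop.
#' @param count Count column to compare (default `"n_esnps"`).
#' @return List with group sizes, means, SDs, `wilcox_p`, `ks_p`,
#'   `excluded`.
#' @export
compare_specific_vs_other <- function(summaries, labels, exclusions = NULL,
                                      count = c("n_esnps",
                                                "n_associations")) {
  count <- match.arg(count)
  m <- merge(summaries, labels, by = "gene")
  m <- m[m$label != "undefined", , drop = FALSE]
  excluded <- intersect(exclusions %||% character(0), m$gene)
  m <- m[!m$gene %in% excluded, , drop = FALSE]
  a <- m[[count]][m$label == "specific_tau_tsi"]
  b <- m[[count]][m$label != "specific_tau_tsi"]
  if (length(a) == 0L || length(b) == 0L) {
    analysis_error("both groups must be non-empty")
  }
  exact <- min(length(a), length(b)) < 50L
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE))
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(n_specific = length(a), n_other = length(b),
       mean_specific = mean(a), sd_specific = stats::sd(a),
       mean_other = mean(b), sd_other = stats::sd(b),
       wilcox_p = w$p.value, ks_p = ks$p.value,
       excluded = excluded)
}

#' Pearson correlations between tissue sample sizes and per-tissue counts
#'
#' For each count column of a per-tissue table (e.g. associations, eSNPs,
#' target genes), the linear correlation with tissue sample size. Constant
#' columns yield `NA` and are flagged.
#'
#' @param per_tissue data.frame with columns `tissue`, `n_samples`, plus one
#'   or more numeric count columns.
#' @return data.frame count_column, pearson_r, flagged.
#' @export
sample_size_correlations <- function(per_tissue) {
  stopifnot_cols(per_tissue, c("tissue", "n_samples"), "per_tissue table")
  if (nrow(per_tissue) < 5L) analysis_error("need >= 5 tissues")
  counts <- setdiff(names(per_tissue), c("tissue", "n_samples"))
  if (length(counts) == 0L) analysis_error("no count columns supplied")
  r <- vapply(counts, function(col) {
    x <- per_tissue[[col]]
    if (length(unique(x)) == 1L || length(unique(per_tissue$n_samples)) == 1L) {
      return(NA_real_)
    }
    stats::cor(per_tissue$n_samples, x, method = "pearson")
  }, numeric(1))
  data.frame(count_column = counts, pearson_r = unname(r),
             flagged = is.na(unname(r)), stringsAsFactors = FALSE)
}
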