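# GWAS-catalog integration: index/LD partition, functional-score comparison,
# selection-signal filtering, enrichment contingency analysis, eSNP
# partition and trait-tissue p-value comparison.

#' Partition SNPs into index and LD proxies per population
#'
#' LD proxies are SNPs with r-squared strictly above `r2_threshold` with at
#' least one index SNP of the same population, restricted to the four
#' reference populations (EUR, ASN, AFR, AMR); index SNPs of mixed or
#' unknown population contribute to index counts only. An LD SNP is counted
#' once per population even when it proxies several index SNPs, and a SNP
#' that is itself an index SNP is never counted as an LD SNP.
#'
#' @param index data.frame with columns `snp_id`, `population`.
#' @param ld data.frame in the `ld` schema.
#' @param r2_threshold Strict lower bound on r-squared, in (0, 1);
#'   default 0.8.
#' @return List with `counts` (data.frame population, n_index, n_ld) and
#'   `roles` (data.frame snp_id, population, role).
#' @export
partition_index_ld <- function(index, ld, r2_threshold = 0.8) {
  if (r2_threshold <= 0 || r2_threshold >= 1) {
    config_error("r2_threshold must be in (0, 1)")
  }
  stopifnot_cols(index, c("snp_id", "population"), "index table")
  bad <- !index$population %in% cyto_vocab$gwas_population
  if (any(bad)) {
    validation_error(sprintf("unknown index population '%s'",
                             index$population[which(bad)[1L]]))
  }
  drop <- !ld$population %in% cyto_vocab$ld_population
  if (any(drop)) {
    warning(sprintf("%d LD record(s) with unrecognized population dropped",
                    sum(drop)))
    ld <- ld[!drop, , drop = FALSE]
  }
  all_index <- unique(index$snp_id)
  counts <- list()
  roles <- list()
  pops <- intersect(cyto_vocab$gwas_population,
                    unique(c(index$population, ld$population)))
  for (pop in pops) {
    idx <- unique(index$snp_id[index$population == pop])
    ld_ids <- character(0)
    if (pop %in% cyto_vocab$ld_population) {
      sub <- ld[ld$population == pop & ld$r2 > r2_threshold, , drop = FALSE]
      partners <- c(sub$snp_b[sub$snp_a %in% idx],
                    sub$snp_a[sub$snp_b %in% idx])
      ld_ids <- setdiff(unique(partners), all_index)
    }
    counts[[length(counts) + 1L]] <-
      data.frame(population = pop, n_index = length(idx),
                 n_ld = length(ld_ids), stringsAsFactors = FALSE)
    roles[[length(roles) + 1L]] <- data.frame(
      snp_id = c(idx, ld_ids),
      population = rep(pop, length(idx) + length(ld_ids)),
      role = c(rep("index", length(idx)), rep("ld", length(ld_ids))),
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, counts), roles = do.call(rbind, roles))
}

#' Two-group proportion test on a 2x2 contingency table
#'
#' Pearson's chi-square with Yates's continuity correction when every
#' expected cell count is at least 5, Fisher's exact test otherwise. Row
#' proportions (first column over row total) are reported as percentages
#' rounded to two decimals alongside the raw values. Tables with a zero
#' margin yield an undefined test, flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows are the two
#'   groups, the first column the outcome of interest.
#' @return List of class `contingency_result`: `counts`, `prop_pct`,
#'   `prop_raw`, `method`, `p_value`, `fdr_p` (equal to `p_value` for a
#'   single table; adjust across tables with [fdr_adjust()]), `flagged`.
#' @export
proportion_test <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    validation_error("need a 2x2 matrix of non-negative integer counts")
  }
  prop_raw <- tab[, 1L] / rowSums(tab)
  res <- list(counts = tab,
              prop_raw = unname(prop_raw),
              prop_pct = unname(round(100 * prop_raw, 2L)),
              method = NA_character_, p_value = NA_real_,
              fdr_p = NA_real_, flagged = FALSE)
  if (any(rowSums(tab) == 0)) {
    res$flagged <- TRUE
    res$method <- "undefined (zero row margin)"
    class(res) <- "contingency_result"
    return(res)
  }
  # a zero column margin means no outcome variation: the exact test gives 1
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(tab, correct = TRUE)
    res$method <- "chi-square (Yates)"
  } else {
    ht <- stats::fisher.test(tab)
    res$method <- "Fisher exact"
  }
  res$p_value <- ht$p.value
  res$fdr_p <- ht$p.value
  class(res) <- "contingency_result"
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (monotone, never below the raw values).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Compare functional-score distributions of index and LD SNPs
#'
#' Two-sample Kolmogorov-Smirnov test of the aggregate functional scores,
#' with group medians. Samples smaller than 3 are flagged as low powered.
#'
#' @param index_scores,ld_scores Non-empty numeric vectors.
#' @return List with `statistic`, `p_value`, `median_index`, `median_ld`,
#'   `low_power`.
#' @export
compare_score_distributions <- function(index_scores, ld_scores) {
  index_scores <- index_scores[!is.na(index_scores)]
  ld_scores <- ld_scores[!is.na(ld_scores)]
  if (length(index_scores) == 0L || length(ld_scores) == 0L) {
    analysis_error("both score samples must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(index_scores, ld_scores))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       median_index = stats::median(index_scores),
       median_ld = stats::median(ld_scores),
       low_power = min(length(index_scores), length(ld_scores)) < 3L)
}

#' Filter selection scores by significant rank score
#'
#' Retains records with rank score strictly above `rank_threshold`
#' (rank scores are -log10 centile ranks; > 2 is the conventional
#' significance level). Each retained record is additionally checked -- but
#' never excluded -- against the statistic's conventional absolute cutoff
#' (Fst >= 0.5, |iHS| >= 2.0).
#'
#' @param scores data.frame in the `selection` schema.
#' @param rank_threshold Strict lower bound on rank score; default 2.
#' @return List with `filtered` (retained records plus a
#'   `meets_abs_cutoff` column) and `conformance` (per-statistic summary of
#'   retained records and how many meet the absolute cutoff).
#' @export
filter_selection <- function(scores, rank_threshold = 2) {
  if (nrow(scores) > 0L) {
    bad <- !scores$statistic %in% cyto_vocab$selection_statistic
    if (any(bad)) {
      validation_error(sprintf("unknown statistic '%s'",
                               scores$statistic[which(bad)[1L]]))
    }
  }
  keep <- scores[scores$rank_score > rank_threshold, , drop = FALSE]
  is_fst <- grepl("^fst", keep$statistic)
  keep$meets_abs_cutoff <- ifelse(is_fst, keep$abs_score >= 0.5,
                                  abs(keep$abs_score) >= 2.0)
  conf <- if (nrow(keep)) {
    do.call(rbind, lapply(split(keep, keep$statistic), function(d) {
      data.frame(statistic = d$statistic[1L], n_retained = nrow(d),
                 n_meeting_abs_cutoff = sum(d$meets_abs_cutoff),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(statistic = character(0), n_retained = integer(0),
               n_meeting_abs_cutoff = integer(0))
  }
  rownames(keep) <- rownames(conf) <- NULL
  list(filtered = keep, conformance = conf)
}

#' Measurement-trait enrichment among selection SNPs
#'
#' Tests whether associations of SNPs under selection are more often
#' measurement-typed than associations of other SNPs. Counting is at the
#' association level (one unit per association record); an association is
#' measurement-typed when its `measurement_type` category list is non-empty
#' (or, with `subtype`, contains a matching entry). The 2x2 table
#' \{selection, other\} x \{measurement, non-measurement\} is tested with
#' [proportion_test()]. Pre-tabulated counts can be supplied directly via
#' `counts`.
#'
#' @param gwas data.frame in the `gwas` schema.
#' @param selection_snps Character vector of SNP ids under selection.
#' @param subtype Optional regular expression restricting the measurement
#'   categories counted (e.g. `"anthropometric"`).
#' @param counts Optional 2x2 matrix (rows selection/other, columns
#'   measurement/non-measurement) bypassing tabulation.
#' @return A `contingency_result` (see [proportion_test()]).
#' @export
measurement_enrichment <- function(gwas = NULL, selection_snps = NULL,
                                   subtype = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot_cols(gwas, c("snp_id", "measurement_type"), "gwas table")
    if (length(selection_snps) == 0L ||
        !any(gwas$snp_id %in% selection_snps)) {
      analysis_error("selection SNP set is empty or disjoint from the table")
    }
    is_sel <- gwas$snp_id %in% selection_snps
    mt <- gwas$measurement_type
    if (!is.list(mt)) mt <- .split_multi(as.character(mt))
    is_meas <- if (is.null(subtype)) {
      lengths(mt) > 0L
    } else {
      vapply(mt, function(m) any(grepl(subtype, m)), logical(1))
    }
    counts <- matrix(c(sum(is_sel & is_meas), sum(is_sel & !is_meas),
                       sum(!is_sel & is_meas), sum(!is_sel & !is_meas)),
                     nrow = 2L, byrow = TRUE,
                     dimnames = list(c("selection", "other"),
                                     c("measurement", "non_measurement")))
  }
  proportion_test(counts)
}

#' Partition GWAS SNPs into eSNPs and non-eSNPs
#'
#' A SNP is an eSNP iff it appears in at least one significant eQTL record.
#' The genomic-region distribution is cross-tabulated by label, and the
#' mean number of eQTL associations per eSNP is reported per region class.
#'
#' @param gwas data.frame with columns `snp_id` and `region_class` (one
#'   region per SNP; the first is used if a SNP repeats), or a character
#'   vector of SNP ids (region columns then omitted).
#' @param eqtls data.frame in the `eqtl` schema.
#' @return List with `labels` (snp_id, label, n_eqtl_associations),
#'   `region_table` (region x label contingency matrix, or NULL) and
#'   `mean_assoc_by_region` (data.frame, or NULL).
#' @export
esnp_partition <- function(gwas, eqtls) {
  if (is.character(gwas)) {
    snps <- unique(gwas)
    region <- NULL
  } else {
    stopifnot_cols(gwas, "snp_id", "gwas table")
    first <- !duplicated(gwas$snp_id)
    snps <- gwas$snp_id[first]
    region <- if ("region_class" %in% names(gwas)) {
      gwas$region_class[first]
    } else NULL
  }
  n_assoc <- as.integer(table(eqtls$snp_id)[snps])
  n_assoc[is.na(n_assoc)] <- 0L
  label <- ifelse(n_assoc > 0L, "eSNP", "non-eSNP")
  labels <- data.frame(snp_id = snps, label = label,
                       n_eqtl_associations = as.integer(n_assoc),
                       stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  region_table <- NULL
  mean_assoc <- NULL
  if (!is.null(region)) {
    region_table <- table(region = region, label = factor(label,
                          levels = c("eSNP", "non-eSNP")))
    es <- labels[labels$label == "eSNP", , drop = FALSE]
    es$region <- region[label == "eSNP"]
    mean_assoc <- do.call(rbind, lapply(split(es, es$region), function(d) {
      data.frame(region_class = d$region[1L],
                 mean_associations = mean(d$n_eqtl_associations),
                 n_esnps = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(mean_assoc) <- NULL
  }
  list(labels = labels, region_table = region_table,
       mean_assoc_by_region = mean_assoc)
}

#' Compare eQTL p-values between tissue categories per trait category
#'
#' For each trait category and each ordered pair of tissue categories, a
#' one-sided rank-sum test of whether eQTL p-values in the first tissue
#' category are lower (i.e. the trait's eQTLs are enriched there) than in
#' the second. P-values are FDR-adjusted across all computed pairs.
#' Category cells with fewer than 3 records are skipped with a notice.
#'
#' @param records data.frame with columns `trait_category`, `tissue`,
#'   `pval` (eQTL association p-values).
#' @param tissue_map data.frame with columns `tissue`, `category`.
#' @param comparisons Optional data.frame `trait_category`, `category_a`,
#'   `category_b` restricting the tested pairs; by default all ordered
#'   pairs of tissue categories present within each trait category.
#' @return data.frame trait_category, category_a, category_b, n_a, n_b,
#'   p_value, fdr_p, note.
#' @export
trait_tissue_comparison <- function(records, tissue_map, comparisons = NULL) {
  stopifnot_cols(records, c("trait_category", "tissue", "pval"),
                 "records table")
  stopifnot_cols(tissue_map, c("tissue", "category"), "tissue_map")
  records$tissue_category <-
    tissue_map$category[match(records$tissue, tissue_map$tissue)]
  records <- records[!is.na(records$tissue_category), , drop = FALSE]
  if (is.null(comparisons)) {
    comparisons <- do.call(rbind, lapply(
      split(records, records$trait_category), function(d) {
        cats <- sort(unique(d$tissue_category))
        if (length(cats) < 2L) return(NULL)
        grid <- expand.grid(category_a = cats, category_b = cats,
                            stringsAsFactors = FALSE)
        grid <- grid[grid$category_a != grid$category_b, , drop = FALSE]
        grid$trait_category <- d$trait_category[1L]
        grid[, c("trait_category", "category_a", "category_b")]
      }))
  }
  if (is.null(comparisons) || nrow(comparisons) == 0L) {
    analysis_error("no tissue-category pairs to compare")
  }
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    tc <- comparisons$trait_category[i]
    sub <- records[records$trait_category == tc, , drop = FALSE]
    a <- sub$pval[sub$tissue_category == comparisons$category_a[i]]
    b <- sub$pval[sub$tissue_category == comparisons$category_b[i]]
    out <- data.frame(trait_category = tc,
                      category_a = comparisons$category_a[i],
                      category_b = comparisons$category_b[i],
                      n_a = length(a), n_b = length(b),
                      p_value = NA_real_, note = "", stringsAsFactors = FALSE)
    if (length(a) < 3L || length(b) < 3L) {
      out$note <- "skipped: fewer than 3 records in a category"
      return(out)
    }
    out$p_value <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "less", exact = FALSE))$p.value
    out
  })
  res <- do.call(rbind, rows)
  res$fdr_p <- NA_real_
  done <- !is.na(res$p_value)
  res$fdr_p[done] <- fdr_adjust(res$p_value[done])
  res[, c("trait_category", "category_a", "category_b", "n_a", "n_b",
          "p_value", "fdr_p", "note")]
}
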