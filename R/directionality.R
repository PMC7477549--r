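# Physical gene clusters and the direction of shared eQTL effects on pairs.

#' Build physical gene clusters by single-linkage chaining
#'
#' Genes on the same chromosome are chained into one cluster whenever the
#' gap between consecutive genes (next start minus previous end) is at most
#' `max_gap_bp`; singletons are dropped. If the catalog supplies explicit
#' `cluster_id` assignments those take precedence and no chaining is done.
#' Genes without coordinates are excluded with a warning.
#'
#' @param catalog data.frame in the `gene_catalog` schema.
#' @param max_gap_bp Maximum inter-gene gap in bp (default 1,000,000).
#' @return data.frame cluster_id, chromosome, symbol, start, end; members
#'   sorted by start within cluster.
#' @export
build_clusters <- function(catalog, max_gap_bp = 1e6) {
  has_coord <- !is.na(catalog$start) & !is.na(catalog$end) &
    !is.na(catalog$chromosome)
  if (any(!has_coord)) {
    warning(sprintf("%d gene(s) without coordinates excluded from clustering",
                    sum(!has_coord)))
  }
  cat2 <- catalog[has_coord, , drop = FALSE]
  explicit <- "cluster_id" %in% names(cat2) && any(!is.na(cat2$cluster_id))
  if (explicit) {
    cl <- cat2[!is.na(cat2$cluster_id), , drop = FALSE]
    cl <- cl[order(cl$cluster_id, cl$start, method = "radix"), , drop = FALSE]
    multi_chrom <- vapply(split(cl$chromosome, cl$cluster_id),
                          function(ch) length(unique(ch)) > 1L, logical(1))
    if (any(multi_chrom)) {
      validation_error(sprintf("cluster(s) span multiple chromosomes: %s",
                               paste(names(multi_chrom)[multi_chrom],
                                     collapse = ", ")))
    }
    keep <- names(which(table(cl$cluster_id) >= 2L))
    cl <- cl[cl$cluster_id %in% keep, , drop = FALSE]
    out <- cl[, c("cluster_id", "chromosome", "symbol", "start", "end")]
    rownames(out) <- NULL
    return(out)
  }
  pieces <- list()
  k <- 0L
  for (ch in sort(unique(cat2$chromosome))) {
    sub <- cat2[cat2$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$symbol, method = "radix"), , drop = FALSE]
    # single linkage: break the chain where the gap exceeds max_gap_bp
    if (nrow(sub) == 1L) {
      grp <- 1L
    } else {
      gap <- sub$start[-1L] - cummax(sub$end)[-nrow(sub)]
      grp <- cumsum(c(TRUE, gap > max_gap_bp))
    }
    for (g in unique(grp)) {
      members <- sub[grp == g, , drop = FALSE]
      if (nrow(members) < 2L) next  # singletons dropped
      k <- k + 1L
      members$cluster_id <- sprintf("CL%04d", k)
      pieces[[length(pieces) + 1L]] <-
        members[, c("cluster_id", "chromosome", "symbol", "start", "end")]
    }
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(cluster_id = character(0), chromosome = character(0),
               symbol = character(0), start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  out
}

#' Classify the direction of a shared eQTL effect on a gene pair
#'
#' Same-signed normalized effect sizes are `unidirectional`, opposite-signed
#' `bidirectional`. Vectorized.
#'
#' @param nes_a,nes_b Nonzero signed effect sizes.
#' @return Character vector in \{`unidirectional`, `bidirectional`\}.
#' @export
classify_direction <- function(nes_a, nes_b) {
  if (any(nes_a == 0) || any(nes_b == 0)) {
    cyto_error("effect sizes must be nonzero", "cytomap_domain_error")
  }
  ifelse(sign(nes_a) == sign(nes_b), "unidirectional", "bidirectional")
}

#' Enumerate shared eQTL effects on clustered gene pairs
#'
#' A shared effect is one (SNP, tissue, unordered gene pair) where both
#' genes belong to the same cluster and both carry a significant eQTL
#' record for that SNP in that tissue. Matching is strictly within tissue.
#' When a SNP hits k genes of a cluster in one tissue, all choose(k, 2)
#' pairs are emitted. Gene pairs are symbol-ordered (gene_a < gene_b).
#'
#' @param eqtls data.frame in the `eqtl` schema.
#' @param clusters data.frame from [build_clusters()].
#' @return data.frame snp_id, tissue, cluster_id, gene_a, gene_b, nes_a,
#'   nes_b, direction.
#' @export
shared_effects <- function(eqtls, clusters) {
  empty <- data.frame(snp_id = character(0), tissue = character(0),
                      cluster_id = character(0), gene_a = character(0),
                      gene_b = character(0), nes_a = numeric(0),
                      nes_b = numeric(0), direction = character(0))
  if (nrow(eqtls) == 0L || nrow(clusters) == 0L) return(empty)
  eq <- merge(eqtls, clusters[, c("symbol", "cluster_id")],
              by.x = "gene", by.y = "symbol")
  if (nrow(eq) == 0L) return(empty)
  # collapse duplicate (snp, tissue, gene) records: keep smallest p-value
  eq <- eq[order(eq$pval, method = "radix"), , drop = FALSE]
  eq <- eq[!duplicated(eq[, c("snp_id", "tissue", "gene")]), , drop = FALSE]
  out <- list()
  for (grp in split(eq, list(eq$cluster_id, eq$snp_id, eq$tissue),
                    drop = TRUE)) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$gene, method = "radix"), , drop = FALSE]
    idx <- utils::combn(nrow(grp), 2L)
    out[[length(out) + 1L]] <- data.frame(
      snp_id = grp$snp_id[1L], tissue = grp$tissue[1L],
      cluster_id = grp$cluster_id[1L],
      gene_a = grp$gene[idx[1L, ]], gene_b = grp$gene[idx[2L, ]],
      nes_a = grp$nes[idx[1L, ]], nes_b = grp$nes[idx[2L, ]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res$direction <- classify_direction(res$nes_a, res$nes_b)
  res <- res[order(res$gene_a, res$gene_b, res$snp_id, res$tissue,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.mean_pairwise_dist_kb <- function(pos) {
  if (length(pos) < 2L) return(NA_real_)
  mean(stats::dist(pos)) / 1000
}

.mean_pairwise_r2 <- function(snps, ld_lookup) {
  if (length(snps) < 2L || is.null(ld_lookup)) {
    return(list(mean_r2 = NA_real_, covered = 0L, total = 0L))
  }
  idx <- utils::combn(sort(snps), 2L)
  keys <- paste(idx[1L, ], idx[2L, ], sep = "\r")
  r2 <- ld_lookup[keys]
  list(mean_r2 = if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE),
       covered = sum(!is.na(r2)), total = length(keys))
}

#' Summarize shared effects per gene pair and compare direction classes
#'
#' Per pair: counts of unidirectional and bidirectional associations
#' (SNP-tissue units), contributing tissue counts per class, the mean
#' pairwise genomic distance (kb) among the distinct SNPs contributing to
#' each class, and the mean pairwise LD r-squared among contributing SNPs
#' (pairs absent from the LD table are omitted from the mean; coverage is
#' reported). Global statistics compare the two direction classes
#' (rank-sum tests on per-pair counts and distances), and report the rank
#' correlation of mean r-squared with distance (one-sided, negative) and of
#' unidirectional with bidirectional counts across pairs (one-sided,
#' negative).
#'
#' @param effects data.frame from [shared_effects()].
#' @param snp_positions Optional data.frame snp_id, position (bp) for
#'   distance summaries; defaults to positions carried in `effects` if a
#'   `position` column is present.
#' @param ld Optional data.frame in the `ld` schema for r-squared summaries.
#' @param ld_population Population whose r-squared values are used
#'   (default `"EUR"`).
#' @return List with `pairs` (one row per gene pair) and `global` (named
#'   list of counts, tests and correlations; comparisons that cannot be
#'   computed are `NA` with a notice in `global$notes`).
#' @export
summarize_pairs <- function(effects, snp_positions = NULL, ld = NULL,
                            ld_population = "EUR") {
  ld_lookup <- NULL
  if (!is.null(ld) && nrow(ld) > 0L) {
    sub <- ld[ld$population == ld_population, , drop = FALSE]
    a <- pmin(sub$snp_a, sub$snp_b)
    b <- pmax(sub$snp_a, sub$snp_b)
    ld_lookup <- stats::setNames(sub$r2, paste(a, b, sep = "\r"))
  }
  pos_lookup <- NULL
  if (!is.null(snp_positions)) {
    pos_lookup <- stats::setNames(snp_positions$position,
                                  snp_positions$snp_id)
  }
  pair_key <- paste(effects$gene_a, effects$gene_b, sep = "\r")
  rows <- list()
  for (key in unique(pair_key)) {
    e <- effects[pair_key == key, , drop = FALSE]
    uni <- e[e$direction == "unidirectional", , drop = FALSE]
    bi <- e[e$direction == "bidirectional", , drop = FALSE]
    dist_of <- function(d) {
      snps <- unique(d$snp_id)
      if (is.null(pos_lookup)) return(NA_real_)
      .mean_pairwise_dist_kb(unname(pos_lookup[snps]))
    }
    r2s <- .mean_pairwise_r2(unique(e$snp_id), ld_lookup)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = e$gene_a[1L], gene_b = e$gene_b[1L],
      n_uni = nrow(uni), n_bi = nrow(bi),
      n_tissues_uni = length(unique(uni$tissue)),
      n_tissues_bi = length(unique(bi$tissue)),
      mean_distance_kb_uni = dist_of(uni),
      mean_distance_kb_bi = dist_of(bi),
      mean_r2 = r2s$mean_r2, r2_pairs_covered = r2s$covered,
      r2_pairs_total = r2s$total,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               n_uni = integer(0), n_bi = integer(0),
               n_tissues_uni = integer(0), n_tissues_bi = integer(0),
               mean_distance_kb_uni = numeric(0),
               mean_distance_kb_bi = numeric(0), mean_r2 = numeric(0),
               r2_pairs_covered = integer(0), r2_pairs_total = integer(0))
  rownames(pairs) <- NULL

  notes <- character(0)
  one_sided_neg_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L) {
      return(list(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           alternative = "less",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  cnt_uni <- pairs$n_uni[pairs$n_uni > 0L]
  cnt_bi <- pairs$n_bi[pairs$n_bi > 0L]
  if (length(cnt_uni) > 0L && length(cnt_bi) > 0L) {
    w_counts <- suppressWarnings(
      stats::wilcox.test(cnt_uni, cnt_bi, exact = FALSE))$p.value
  } else {
    w_counts <- NA_real_
    notes <- c(notes, "one direction class empty: count comparison skipped")
  }
  d_uni <- pairs$mean_distance_kb_uni[!is.na(pairs$mean_distance_kb_uni)]
  d_bi <- pairs$mean_distance_kb_bi[!is.na(pairs$mean_distance_kb_bi)]
  if (length(d_uni) > 0L && length(d_bi) > 0L) {
    w_dist <- suppressWarnings(
      stats::wilcox.test(d_uni, d_bi, exact = FALSE))$p.value
  } else {
    w_dist <- NA_real_
    notes <- c(notes, "distances unavailable: distance comparison skipped")
  }
  mean_dist_all <- rowMeans(
    cbind(pairs$mean_distance_kb_uni, pairs$mean_distance_kb_bi),
    na.rm = TRUE)
  mean_dist_all[is.nan(mean_dist_all)] <- NA_real_
  c_r2 <- one_sided_neg_cor(pairs$mean_r2, mean_dist_all)
  c_dir <- one_sided_neg_cor(pairs$n_uni, pairs$n_bi)

  total <- nrow(effects)
  global <- list(
    n_effects = total,
    n_effects_uni = sum(pairs$n_uni), n_effects_bi = sum(pairs$n_bi),
    n_pairs = nrow(pairs),
    n_pairs_with_uni = sum(pairs$n_uni > 0L),
    n_pairs_with_bi = sum(pairs$n_bi > 0L),
    bidirectional_fraction = if (total > 0L) sum(pairs$n_bi) / total else
      NA_real_,
    mean_count_uni = if (length(cnt_uni)) mean(cnt_uni) else NA_real_,
    sd_count_uni = if (length(cnt_uni) > 1L) stats::sd(cnt_uni) else NA_real_,
    mean_count_bi = if (length(cnt_bi)) mean(cnt_bi) else NA_real_,
    sd_count_bi = if (length(cnt_bi) > 1L) stats::sd(cnt_bi) else NA_real_,
    mean_dist_uni = if (length(d_uni)) mean(d_uni) else NA_real_,
    mean_dist_bi = if (length(d_bi)) mean(d_bi) else NA_real_,
    wilcox_p_counts = w_counts,
    wilcox_p_distances = w_dist,
    spearman_r2_vs_distance = c_r2$rho,
    spearman_r2_vs_distance_p = c_r2$p,
    spearman_uni_vs_bi = c_dir$rho,
    spearman_uni_vs_bi_p = c_dir$p,
    notes = notes)
  list(pairs = pairs, global = global)
}
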