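test_that("index/LD partition applies the strict r2 threshold per population", {
  index <- data.frame(snp_id = c("rs1", "rs2"), population = c("EUR", "ASN"))
  ld <- validate_records(
    data.frame(snp_a = c("rs1", "rs1", "rs2", "rs1"),
               snp_b = c("p1", "p2", "p3", "p4"),
               population = c("EUR", "EUR", "ASN", "ASN"),
               r2 = c(0.8, 0.85, 0.9, 0.99)), "ld")
  part <- partition_index_ld(index, ld)
  # r2 = 0.8 exactly is excluded; rs1 is not an ASN index SNP
  eur <- part$counts[part$counts$population == "EUR", ]
  asn <- part$counts[part$counts$population == "ASN", ]
  expect_equal(eur$n_ld, 1L)   # p2 only
  expect_equal(asn$n_ld, 1L)   # p3 only (p4 proxies a non-ASN index SNP)
  expect_equal(eur$n_index, 1L)

  # index SNP with no partners contributes only to index counts
  part2 <- partition_index_ld(data.frame(snp_id = "rs9",
                                         population = "EUR"), ld[0, ])
  expect_equal(part2$counts$n_index, 1L)
  expect_equal(part2$counts$n_ld, 0L)
})

test_that("partition is exhaustive and matches brute-force enumeration", {
  set.seed(404)
  index <- data.frame(snp_id = sprintf("rs%02d", 1:8),
                      population = rep(c("EUR", "ASN"), each = 4))
  pairs <- expand.grid(snp_a = sprintf("rs%02d", 1:8),
                       snp_b = sprintf("pp%02d", 1:12),
                       stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 40), ]
  pairs$population <- sample(c("EUR", "ASN"), 40, replace = TRUE)
  pairs$r2 <- stats::runif(40)
  ld <- validate_records(pairs, "ld")
  part <- partition_index_ld(index, ld)
  for (pop in c("EUR", "ASN")) {
    idx <- index$snp_id[index$population == pop]
    # brute force: scan every pair record for a qualifying partner
    partners <- character(0)
    for (i in seq_len(nrow(ld))) {
      if (ld$population[i] != pop || ld$r2[i] <= 0.8) next
      if (ld$snp_a[i] %in% idx) partners <- c(partners, ld$snp_b[i])
      if (ld$snp_b[i] %in% idx) partners <- c(partners, ld$snp_a[i])
    }
    partners <- setdiff(unique(partners), index$snp_id)
    expect_equal(part$counts$n_ld[part$counts$population == pop],
                 length(partners))
    roles <- part$roles[part$roles$population == pop, ]
    expect_setequal(roles$snp_id[roles$role == "ld"], partners)
    # completeness: every SNP has exactly one role per population
    expect_equal(anyDuplicated(roles$snp_id), 0L)
  }
})

test_that("mixed and unknown populations contribute index SNPs only", {
  index <- data.frame(snp_id = c("rs1", "rs2"),
                      population = c("MIXED", "UNKNOWN"))
  part <- partition_index_ld(index,
                             validate_records(
                               data.frame(snp_a = "rs1", snp_b = "p1",
                                          population = "EUR", r2 = 0.95),
                               "ld"))
  expect_true(all(part$roles$role == "index"))
})

test_that("proportion test reproduces printed proportions and picks its test", {
  res <- proportion_test(matrix(c(348, 61, 1865, 789), 2, byrow = TRUE))
  expect_equal(res$prop_pct, c(85.09, 70.27))
  expect_identical(res$method, "chi-square (Yates)")
  expect_equal(res$p_value,
               stats::chisq.test(matrix(c(348, 61, 1865, 789), 2,
                                        byrow = TRUE))$p.value)
  # identical rows -> p = 1 under the exact test
  res2 <- proportion_test(matrix(c(3, 2, 3, 2), 2, byrow = TRUE))
  expect_identical(res2$method, "Fisher exact")
  expect_equal(res2$p_value, 1)
  # balanced table matches the hypergeometric oracle
  tab <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(proportion_test(tab)$p_value, oracle_fisher_p(tab))
  # zero margin flagged
  expect_true(proportion_test(matrix(c(0, 0, 3, 4), 2,
                                     byrow = TRUE))$flagged)
})

test_that("functional-score comparison handles identical/disjoint samples", {
  x <- stats::rnorm(50)
  res <- compare_score_distributions(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- compare_score_distributions(stats::runif(50, 10, 11),
                                      stats::runif(50, 0, 1))
  expect_equal(res2$statistic, 1)
  expect_true(compare_score_distributions(1:2, 3:9)$low_power)
  expect_error(compare_score_distributions(numeric(0), 1:3),
               class = "cytomap_analysis_error")
})

test_that("selection filtering is strict on rank score, advisory on cutoffs", {
  sc <- validate_records(
    data.frame(snp_id = paste0("rs", 1:4),
               statistic = c("fst_global", "fst_global", "ihs_ceu",
                             "ihs_ceu"),
               abs_score = c(0.6, 0.3, -2.5, 1.0),
               rank_score = c(2.5, 2.0, 3.0, 2.2)), "selection")
  fs <- filter_selection(sc)
  # rank 2.0 exactly is excluded
  expect_setequal(fs$filtered$snp_id, c("rs1", "rs3", "rs4"))
  expect_identical(fs$filtered$meets_abs_cutoff[
    match(c("rs1", "rs3", "rs4"), fs$filtered$snp_id)],
    c(TRUE, TRUE, FALSE))
  expect_equal(nrow(filter_selection(sc[0, ])$filtered), 0L)
  sc_bad <- sc
  sc_bad$statistic[1] <- "mystery"
  expect_error(filter_selection(sc_bad), class = "cytomap_validation_error")
})

test_that("selection filtering equals a filter-comprehension oracle", {
  set.seed(505)
  sc <- validate_records(
    data.frame(snp_id = paste0("rs", 1:30),
               statistic = sample(c("fst_global", "fst_ceu_chb", "ihs_ceu",
                                    "ihs_yri"), 30, replace = TRUE),
               abs_score = stats::runif(30, -3, 3),
               rank_score = stats::runif(30, 0, 4)), "selection")
  fs <- filter_selection(sc)
  keep <- sc$snp_id[sc$rank_score > 2]
  expect_setequal(fs$filtered$snp_id, keep)
  for (k in seq_len(nrow(fs$filtered))) {
    row <- fs$filtered[k, ]
    expected <- if (grepl("^fst", row$statistic)) row$abs_score >= 0.5 else
      abs(row$abs_score) >= 2
    expect_identical(row$meets_abs_cutoff, expected)
  }
})

test_that("measurement enrichment tabulates at the association level", {
  gwas <- validate_records(
    data.frame(snp_id = c("rs1", "rs1", "rs2", "rs3"),
               mapped_genes = "G1", trait = "x",
               disease_type = "", anatomical_system = "",
               measurement_type = c("protein measurement", "",
                                    "protein measurement",
                                    "protein measurement"),
               disease = "", population = "EUR",
               region_class = "intronic"), "gwas")
  res <- measurement_enrichment(gwas, selection_snps = "rs1")
  expect_equal(unname(res$counts["selection", ]), c(1, 1))
  expect_equal(unname(res$counts["other", ]), c(2, 0))
  expect_error(measurement_enrichment(gwas, selection_snps = "rs99"),
               class = "cytomap_analysis_error")
  # all associations measurement-typed -> both proportions 100, p = 1
  gw2 <- gwas
  gw2$measurement_type <- list("protein measurement")
  res2 <- measurement_enrichment(gw2, selection_snps = "rs1")
  expect_equal(res2$prop_pct, c(100, 100))
  expect_equal(res2$p_value, 1)
})

test_that("eSNP/non-eSNP partition is set membership in the eQTL table", {
  eq <- make_eqtl(c("rs1", "rs1", "rs2"), "G1", c("t1", "t2", "t1"),
                  c(0.5, 0.3, -0.2))
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     region_class = c("intronic", "intergenic_other",
                                      "intronic"))
  ep <- esnp_partition(gwas, eq)
  expect_identical(ep$labels$label, c("eSNP", "eSNP", "non-eSNP"))
  expect_equal(ep$labels$n_eqtl_associations, c(2L, 1L, 0L))
  expect_equal(unname(ep$region_table["intronic", "eSNP"]), 1L)
  expect_equal(unname(ep$region_table["intronic", "non-eSNP"]), 1L)
  ma <- ep$mean_assoc_by_region
  expect_equal(ma$mean_associations[ma$region_class == "intronic"], 2)
  # every GWAS SNP present -> zero non-eSNPs
  ep2 <- esnp_partition(c("rs1", "rs2"), eq)
  expect_true(all(ep2$labels$label == "eSNP"))
})

test_that("50-SNP partition equals a set-membership oracle", {
  set.seed(606)
  eq <- random_eqtl_fixture(120, paste0("G", 1:6), paste0("t", 1:4),
                            sprintf("rs%03d", 1:40))
  snps <- sprintf("rs%03d", sample(1:80, 50))
  ep <- esnp_partition(snps, eq)
  for (s in snps) {
    expect_identical(ep$labels$label[ep$labels$snp_id == s],
                     if (s %in% eq$snp_id) "eSNP" else "non-eSNP")
  }
})

test_that("trait-tissue comparison detects planted p-value shifts", {
  tissue_map <- data.frame(tissue = c("brain1", "brain2", "skin1", "skin2"),
                           category = c("nervous", "nervous",
                                        "integumentary", "integumentary"))
  # identical p-value sets -> no enrichment either way
  rec_same <- data.frame(trait_category = "nervous_disease",
                         tissue = rep(c("brain1", "skin1"), each = 10),
                         pval = rep(10^-(1:10), 2))
  res_same <- trait_tissue_comparison(rec_same, tissue_map)
  expect_true(all(res_same$p_value > 0.4))

  # all nervous p-values below all others -> minimal attainable one-sided p
  rec_ext <- data.frame(trait_category = "nervous_disease",
                        tissue = rep(c("brain1", "skin1"), each = 8),
                        pval = c(10^-(20:27), 10^-(1:8)))
  res_ext <- trait_tissue_comparison(rec_ext, tissue_map)
  row <- res_ext[res_ext$category_a == "nervous", ]
  expect_equal(row$p_value,
               suppressWarnings(
                 stats::wilcox.test(10^-(20:27), 10^-(1:8),
                                    alternative = "less",
                                    exact = FALSE)$p.value))
  expect_lt(row$p_value, 0.001)

  # small cells are skipped with a notice
  rec_small <- data.frame(trait_category = "x",
                          tissue = c("brain1", "brain1", "skin1", "skin1",
                                     "skin1"),
                          pval = c(0.1, 0.2, 0.3, 0.4, 0.5))
  res_small <- trait_tissue_comparison(rec_small, tissue_map)
  expect_true(all(grepl("skipped", res_small$note)))
})

test_that("planted shift direction is recovered in virtually all replicates", {
  set.seed(707)
  tissue_map <- data.frame(tissue = c("a1", "b1"),
                           category = c("catA", "catB"))
  hits <- 0L
  for (rep in 1:100) {
    rec <- data.frame(trait_category = "d",
                      tissue = rep(c("a1", "b1"), each = 30),
                      pval = c(stats::runif(30, 1e-12, 1e-8),
                               stats::runif(30, 1e-4, 1e-2)))
    res <- trait_tissue_comparison(rec, tissue_map)
    p_fwd <- res$p_value[res$category_a == "catA"]
    p_rev <- res$p_value[res$category_a == "catB"]
    if (!is.na(p_fwd) && p_fwd < 0.05 && p_fwd < p_rev) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("FDR adjustment is monotone and matches the step-up oracle", {
  set.seed(808)
  for (rep in 1:10) {
    p <- stats::runif(sample(3:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
  }
})
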