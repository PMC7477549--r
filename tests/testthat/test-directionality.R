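test_that("single-linkage chaining respects the gap threshold", {
  # two genes 10 kb apart -> one cluster
  cat1 <- make_catalog(c("A", "B"), start = c(1e6, 1e6 + 6e4),
                       end = c(1e6 + 5e4, 1e6 + 11e4))
  cl1 <- build_clusters(cat1)
  expect_equal(length(unique(cl1$cluster_id)), 1L)
  expect_equal(nrow(cl1), 2L)

  # same positions on different chromosomes -> never clustered (singletons drop)
  cat2 <- make_catalog(c("A", "B"), chrom = c("chr1", "chr2"),
                       start = c(1e6, 1e6 + 6e4),
                       end = c(1e6 + 5e4, 1e6 + 11e4))
  expect_equal(nrow(build_clusters(cat2)), 0L)

  # chain A-B-C with 0.5 Mb gaps -> one 3-gene cluster under single linkage
  cat3 <- make_catalog(c("A", "B", "C"),
                       start = c(1e6, 1.55e6, 2.10e6),
                       end = c(1.05e6, 1.60e6, 2.15e6))
  cl3 <- build_clusters(cat3)
  expect_equal(length(unique(cl3$cluster_id)), 1L)
  expect_identical(cl3$symbol, c("A", "B", "C"))

  # gap above the threshold splits the chain; singleton side is dropped
  cl4 <- build_clusters(cat3, max_gap_bp = 4.9e5)
  expect_equal(nrow(cl4), 0L)
})

test_that("explicit catalog cluster assignments take precedence", {
  cat <- make_catalog(c("A", "B", "C", "D"),
                      start = c(1e6, 2e6, 50e6, 51e6),
                      end = c(1.1e6, 2.1e6, 50.1e6, 51.1e6),
                      cluster_id = c("K1", "K1", NA, NA))
  cl <- build_clusters(cat)
  expect_identical(sort(cl$symbol), c("A", "B"))
  expect_identical(unique(cl$cluster_id), "K1")
})

test_that("genes without coordinates are excluded with a warning", {
  cat <- make_catalog(c("A", "B", "C"))
  cat$start[3] <- NA
  cat$end[3] <- NA
  expect_warning(cl <- build_clusters(cat), "without coordinates")
  expect_false("C" %in% cl$symbol)
})

test_that("effect direction is the sign comparison of the two NES values", {
  expect_identical(classify_direction(0.3, 1.2), "unidirectional")
  expect_identical(classify_direction(0.3, -0.1), "bidirectional")
  expect_identical(classify_direction(-2, -0.01), "unidirectional")
  expect_identical(classify_direction(c(1, -1), c(1, 1)),
                   c("unidirectional", "bidirectional"))
  expect_error(classify_direction(0, 1), class = "cytomap_domain_error")
})

test_that("shared-effect enumeration covers pair combinatorics", {
  cat <- make_catalog(c("A", "B", "C"), cluster_id = "K1")
  cl <- build_clusters(cat)
  # SNP hitting one gene only -> no shared effect
  eq1 <- make_eqtl("rs1", "A", "t1", 0.5)
  expect_equal(nrow(shared_effects(eq1, cl)), 0L)
  # SNP hitting 3 cluster genes in one tissue -> 3 pair records
  eq3 <- make_eqtl("rs1", c("A", "B", "C"), "t1", c(0.5, -0.2, 0.1))
  se <- shared_effects(eq3, cl)
  expect_equal(nrow(se), 3L)
  expect_true(all(se$gene_a < se$gene_b))
  expect_identical(se$direction[se$gene_a == "A" & se$gene_b == "B"],
                   "bidirectional")
  expect_identical(se$direction[se$gene_a == "A" & se$gene_b == "C"],
                   "unidirectional")
})

test_that("shared effects equal a brute-force triple-loop enumeration", {
  set.seed(123)
  for (rep in 1:3) {
    cat <- rbind(make_catalog(paste0("A", 1:3), cluster_id = "K1"),
                 make_catalog(paste0("B", 1:4), chrom = "chr2",
                              cluster_id = "K2"))
    cl <- build_clusters(cat)
    eq <- random_eqtl_fixture(200, c(paste0("A", 1:3), paste0("B", 1:4)),
                              paste0("t", 1:4), paste0("rs", 1:12))
    se <- shared_effects(eq, cl)
    oracle <- oracle_shared_effects(eq, cl)
    expect_equal(nrow(se), nrow(oracle))
    expect_identical(se[, c("snp_id", "tissue", "gene_a", "gene_b",
                            "direction")],
                     oracle[, c("snp_id", "tissue", "gene_a", "gene_b",
                                "direction")],
                     ignore_attr = TRUE)
    # partition invariant: every effect is exactly one direction class
    sp <- summarize_pairs(se)
    expect_equal(sum(sp$pairs$n_uni) + sum(sp$pairs$n_bi), nrow(se))
  }
})

test_that("results are invariant under swapping input gene labels", {
  set.seed(321)
  cat <- make_catalog(c("A", "B"), cluster_id = "K1")
  cl <- build_clusters(cat)
  eq <- random_eqtl_fixture(60, c("A", "B"), paste0("t", 1:5),
                            paste0("rs", 1:8))
  eq_swapped <- eq
  eq_swapped$gene <- ifelse(eq$gene == "A", "B", "A")
  se <- shared_effects(eq, cl)
  se2 <- shared_effects(eq_swapped, cl)
  # same effects, with the roles of the two genes exchanged
  expect_equal(nrow(se), nrow(se2))
  key <- function(d) sort(paste(d$snp_id, d$tissue, d$direction))
  expect_identical(key(se), key(se2))
})

test_that("pair summaries report distances, LD and direction comparisons", {
  cat <- make_catalog(c("A", "B"), cluster_id = "K1")
  cl <- build_clusters(cat)
  # single shared effect: count 1, undefined pairwise distance
  eq1 <- make_eqtl("rs1", c("A", "B"), "t1", c(0.5, 0.7))
  sp1 <- summarize_pairs(shared_effects(eq1, cl),
                         snp_positions = data.frame(snp_id = "rs1",
                                                    position = 1e6))
  expect_equal(sp1$pairs$n_uni + sp1$pairs$n_bi, 1L)
  expect_true(is.na(sp1$pairs$mean_distance_kb_uni))

  # all same-signed -> bidirectional side empty, comparison skipped
  eq2 <- rbind(make_eqtl("rs1", c("A", "B"), "t1", c(0.5, 0.7)),
               make_eqtl("rs2", c("A", "B"), "t1", c(0.2, 0.9)))
  sp2 <- summarize_pairs(shared_effects(eq2, cl))
  expect_equal(sp2$global$n_effects_bi, 0L)
  expect_true(is.na(sp2$global$wilcox_p_counts))
  expect_true(any(grepl("skipped", sp2$global$notes)))

  # distances: two SNPs 100 kb apart, both unidirectional
  pos <- data.frame(snp_id = c("rs1", "rs2"), position = c(1e6, 1.1e6))
  sp3 <- summarize_pairs(shared_effects(eq2, cl), snp_positions = pos)
  expect_equal(sp3$pairs$mean_distance_kb_uni, 100)

  # mean r2 over contributing SNP pairs, EUR by default
  ld <- validate_records(
    data.frame(snp_a = "rs1", snp_b = "rs2",
               population = c("EUR", "ASN"), r2 = c(0.9, 0.2)), "ld")
  sp4 <- summarize_pairs(shared_effects(eq2, cl), snp_positions = pos,
                         ld = ld)
  expect_equal(sp4$pairs$mean_r2, 0.9)
  expect_equal(sp4$pairs$r2_pairs_covered, 1L)
})

test_that("planted bidirectional probabilities are recovered on a grid", {
  for (p in c(0.1, 0.3, 0.5)) {
    cfg <- sim_config(seed = 100 + round(100 * p), n_genes = 60,
                      n_clusters = 6, genes_per_cluster = 4,
                      n_eqtl_snps = 600, p_bidirectional = p,
                      eqtl_rate_specific = 0, eqtl_rate_other = 0)
    cat <- gen_catalog(cfg)
    eq <- gen_eqtl(cfg, cat)
    se <- shared_effects(eq$eqtl, build_clusters(cat))
    # SNP-level recovery: one planted direction per shared SNP
    per_snp <- unique(se[, c("snp_id", "direction")])
    est <- mean(per_snp$direction == "bidirectional")
    se3 <- 3 * sqrt(p * (1 - p) / nrow(per_snp))
    expect_lt(abs(est - p), se3)
    # and agreement with the generator's own truth table
    expect_equal(est, mean(eq$truth$bidirectional))
  }
})
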