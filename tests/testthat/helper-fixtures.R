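# Shared fixture builders and independent oracles used across test files.

make_catalog <- function(symbols, chrom = "chr1", start = NULL, end = NULL,
                         cluster_id = NA_character_) {
  n <- length(symbols)
  if (is.null(start)) start <- seq(1e6, by = 2e5, length.out = n)
  if (is.null(end)) end <- start + 5e4
  validate_records(
    data.frame(symbol = symbols, chromosome = rep_len(chrom, n),
               start = start, end = end,
               activity_classes = I(rep(list("cytokine_activity"), n)),
               cluster_id = rep_len(cluster_id, n),
               stringsAsFactors = FALSE),
    "gene_catalog")
}

make_eqtl <- function(snp_id, gene, tissue, nes, pval = 1e-6,
                      chromosome = "chr1", position = 1e6) {
  n <- length(nes)
  validate_records(
    data.frame(snp_id = rep_len(snp_id, n), chromosome = rep_len(chromosome, n),
               position = rep_len(position, n), gene = rep_len(gene, n),
               tissue = rep_len(tissue, n), nes = nes,
               pval = rep_len(pval, n), stringsAsFactors = FALSE),
    "eqtl")
}

# random (snp, gene, tissue) eqtl table without duplicate triples
random_eqtl_fixture <- function(n, genes, tissues, snps) {
  grid <- expand.grid(snp_id = snps, gene = genes, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), min(n, nrow(grid))), , drop = FALSE]
  grid$chromosome <- "chr1"
  grid$position <- sample(1e6:2e6, nrow(grid), replace = TRUE)
  grid$nes <- stats::runif(nrow(grid), -2, 2)
  grid$nes[grid$nes == 0] <- 0.1
  grid$pval <- stats::runif(nrow(grid), 1e-12, 1e-4)
  rownames(grid) <- NULL
  validate_records(grid[, c("snp_id", "chromosome", "position", "gene",
                            "tissue", "nes", "pval")], "eqtl")
}

# independent brute-force enumeration of shared effects (triple loop)
oracle_shared_effects <- function(eqtls, clusters) {
  rows <- list()
  for (cid in unique(clusters$cluster_id)) {
    members <- sort(clusters$symbol[clusters$cluster_id == cid])
    if (length(members) < 2L) next
    for (snp in unique(eqtls$snp_id)) {
      for (tis in unique(eqtls$tissue)) {
        for (i in seq_along(members)) {
          for (j in seq_along(members)) {
            if (i >= j) next
            ra <- eqtls[eqtls$snp_id == snp & eqtls$tissue == tis &
                          eqtls$gene == members[i], , drop = FALSE]
            rb <- eqtls[eqtls$snp_id == snp & eqtls$tissue == tis &
                          eqtls$gene == members[j], , drop = FALSE]
            if (nrow(ra) == 0L || nrow(rb) == 0L) next
            dir <- if (sign(ra$nes[1L]) == sign(rb$nes[1L]))
              "unidirectional" else "bidirectional"
            rows[[length(rows) + 1L]] <- data.frame(
              snp_id = snp, tissue = tis, gene_a = members[i],
              gene_b = members[j], direction = dir, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(snp_id = character(0), tissue = character(0),
                      gene_a = character(0), gene_b = character(0),
                      direction = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b, out$snp_id, out$tissue,
            method = "radix"), , drop = FALSE]
}

# independent hypergeometric enumeration of the two-sided Fisher p-value
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  x <- max(0L, k - r2):min(k, r1)
  probs <- stats::dhyper(x, r1, r2, k)
  sum(probs[probs <= stats::dhyper(tab[1L, 1L], r1, r2, k) * (1 + 1e-7)])
}

# independent step-up BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
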