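# Jaccard tissue similarity over direction-signed eQTL target signatures.

#' Build per-tissue eQTL signatures
#'
#' A tissue's signature is the set of (SNP, target gene, NES sign) triples
#' among its significant eQTL records (set semantics: duplicates collapse).
#' Optional filters restrict to a gene set and/or SNP set before
#' collection, implementing the three analysis sets (catalog targets of
#' GWAS eSNPs; all targets of GWAS eSNPs; catalog targets genome-wide).
#' With `match_on = "gene_sign"` the SNP is dropped from the triple so
#' overlap is registered on target gene and effect direction only.
#'
#' @param eqtls data.frame in the `eqtl` schema.
#' @param gene_filter Optional character vector of gene symbols to keep.
#' @param snp_filter Optional character vector of SNP ids to keep.
#' @param match_on `"triple"` (SNP + gene + sign, default) or
#'   `"gene_sign"`.
#' @return Named list (one element per tissue present after filtering) of
#'   character sets encoding the triples.
#' @export
build_signatures <- function(eqtls, gene_filter = NULL, snp_filter = NULL,
                             match_on = c("triple", "gene_sign")) {
  match_on <- match.arg(match_on)
  eq <- eqtls
  if (!is.null(gene_filter)) eq <- eq[eq$gene %in% gene_filter, , drop = FALSE]
  if (!is.null(snp_filter)) eq <- eq[eq$snp_id %in% snp_filter, , drop = FALSE]
  if (nrow(eq) == 0L) return(stats::setNames(list(), character(0)))
  key <- if (match_on == "triple") {
    paste(eq$snp_id, eq$gene, ifelse(eq$nes > 0, "+1", "-1"), sep = "|")
  } else {
    paste(eq$gene, ifelse(eq$nes > 0, "+1", "-1"), sep = "|")
  }
  sigs <- lapply(split(key, eq$tissue), unique)
  sigs[order(names(sigs))]
}

#' Pairwise Jaccard similarity matrix between tissue signatures
#'
#' J(A, B) = 100 * |A intersect B| / |A union B| for every tissue pair,
#' reported on the 0-100 scale (the raw 0-1 matrix is also returned).
#' A pair of two empty signatures is defined as 0 and flagged. The diagonal
#' is 100.
#'
#' @param signatures Named list from [build_signatures()]; >= 2 tissues.
#' @return List with `jaccard` (0-100 matrix), `raw` (0-1 matrix),
#'   `mean_offdiag`, `sd_offdiag`, `range_offdiag` (all on the 0-100
#'   scale), and `empty_pairs` (data.frame of flagged both-empty pairs).
#' @export
jaccard_matrix <- function(signatures) {
  n <- length(signatures)
  if (n < 2L) analysis_error("need >= 2 tissue signatures")
  tissues <- names(signatures)
  raw <- matrix(1, n, n, dimnames = list(tissues, tissues))
  empty_a <- empty_b <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- signatures[[i]]
      b <- signatures[[j]]
      u <- length(union(a, b))
      if (u == 0L) {
        raw[i, j] <- raw[j, i] <- 0
        empty_a <- c(empty_a, tissues[i])
        empty_b <- c(empty_b, tissues[j])
      } else {
        raw[i, j] <- raw[j, i] <- length(intersect(a, b)) / u
      }
    }
  }
  off <- 100 * raw[upper.tri(raw)]
  list(jaccard = 100 * raw, raw = raw,
       mean_offdiag = mean(off), sd_offdiag = stats::sd(off),
       range_offdiag = range(off),
       empty_pairs = data.frame(tissue_a = empty_a, tissue_b = empty_b,
                                stringsAsFactors = FALSE))
}
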