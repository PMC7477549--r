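# Tissue-specificity metrics (Tau, TSI) and cross-tissue expression summaries.

.check_profile <- function(x) {
  if (length(x) < 2L) cyto_error("profile needs >= 2 tissues", "cytomap_domain_error")
  if (anyNA(x)) cyto_error("profile contains NA", "cytomap_domain_error")
  if (any(x < 0)) cyto_error("negative expression value", "cytomap_domain_error")
  if (all(x == 0)) cyto_error("all-zero profile: specificity undefined",
                              "cytomap_undefined_score")
  invisible(x)
}

#' Tau tissue-specificity metric
#'
#' Tau = sum_i (1 - x_i / x_max) / (N - 1) over an N-tissue expression
#' profile. Tau is 0 for a profile constant across tissues and 1 when
#' expression is confined to a single tissue; it is invariant to rescaling
#' of the profile.
#'
#' @param x Non-negative numeric vector of length >= 2 (one expression value
#'   per tissue, typically median TPM), not all zero.
#' @return Tau in \[0, 1\].
#' @examples
#' compute_tau(c(8, 2, 2, 2))  # 0.75
#' @export
compute_tau <- function(x) {
  .check_profile(x)
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' TSI tissue-specificity index
#'
#' TSI = x_max / sum_i x_i. Ranges from 1/N (uniform profile) to 1
#' (single-tissue expression); scale-invariant.
#'
#' @inheritParams compute_tau
#' @return TSI in \[1/N, 1\].
#' @examples
#' compute_tsi(c(8, 2, 2, 2))  # 8/14
#' @export
compute_tsi <- function(x) {
  .check_profile(x)
  max(x) / sum(x)
}

#' Score every gene of an expression matrix for tissue specificity
#'
#' Computes Tau and TSI per gene together with the number of expressing
#' tissues, the top tissue and its expression level. Genes with an all-zero
#' profile (not detected in any tissue) are retained with `NA` scores so
#' catalog counts reconcile. Ties for the top tissue are broken by
#' lexicographic tissue name and flagged in `top_tie`.
#'
#' @param mat Numeric gene-by-tissue matrix (e.g. from
#'   [read_expression_gct()]); >= 2 tissues, non-negative.
#' @param log2_offset If `TRUE`, scores are computed on log2(x + 1)
#'   transformed values (the metrics' original definition uses the raw
#'   scale, which is the default).
#' @return data.frame with columns gene, tau, tsi, n_expressed, top_tissue,
#'   top_tpm, top_tie. `top_tpm` is always on the raw TPM scale.
#' @export
score_matrix <- function(mat, log2_offset = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (any(mat < 0)) cyto_error("negative expression value", "cytomap_domain_error")
  work <- if (log2_offset) log2(mat + 1) else mat
  n <- nrow(mat)
  tau <- tsi <- top_tpm <- rep(NA_real_, n)
  n_expressed <- integer(n)
  top_tissue <- rep(NA_character_, n)
  top_tie <- logical(n)
  tissue_order <- order(colnames(mat))
  for (i in seq_len(n)) {
    x <- work[i, ]
    n_expressed[i] <- sum(mat[i, ] > 0)
    if (all(x == 0)) next
    tau[i] <- compute_tau(x)
    tsi[i] <- compute_tsi(x)
    xo <- x[tissue_order]
    j <- tissue_order[which.max(xo)]        # lexicographic tie-break
    top_tissue[i] <- colnames(mat)[j]
    top_tpm[i] <- mat[i, j]
    top_tie[i] <- sum(x == max(x)) > 1L
  }
  data.frame(gene = rownames(mat) %||% as.character(seq_len(n)),
             tau = tau, tsi = tsi, n_expressed = n_expressed,
             top_tissue = top_tissue, top_tpm = top_tpm, top_tie = top_tie,
             stringsAsFactors = FALSE)
}

#' Classify genes as tissue-specific from their Tau and TSI scores
#'
#' Thresholds are inclusive: a gene is `specific_tau` when Tau >= `tau_thr`,
#' and `specific_tau_tsi` when additionally TSI >= `tsi_thr`. Genes below
#' the Tau threshold are `nonspecific`; genes with undefined scores
#' (all-zero profiles) are `undefined`.
#'
#' @param scores data.frame from [score_matrix()].
#' @param tau_thr Tau threshold in (0, 1\]; default 0.8.
#' @param tsi_thr TSI threshold in (0, 1\]; default 0.3.
#' @return data.frame with columns gene, label (one of `specific_tau_tsi`,
#'   `specific_tau`, `nonspecific`, `undefined`).
#' @export
classify_specific <- function(scores, tau_thr = 0.8, tsi_thr = 0.3) {
  stopifnot(tau_thr > 0, tau_thr <= 1, tsi_thr > 0, tsi_thr <= 1)
  label <- ifelse(is.na(scores$tau), "undefined",
           ifelse(scores$tau >= tau_thr & scores$tsi >= tsi_thr, "specific_tau_tsi",
           ifelse(scores$tau >= tau_thr, "specific_tau", "nonspecific")))
  data.frame(gene = scores$gene, label = label, stringsAsFactors = FALSE)
}

#' Tissue-pairwise rank correlation of gene expression
#'
#' Spearman rank correlation (midranks for ties) between every pair of
#' tissue columns. Pairs involving a constant column have undefined
#' correlation; they are flagged and excluded from the reported mean/range.
#'
#' @param mat Gene-by-tissue matrix with >= 3 genes.
#' @return List with `matrix` (symmetric, unit diagonal), `mean_offdiag`,
#'   `range_offdiag`, and `constant_tissues` (names of flagged columns).
#' @export
tissue_correlation <- function(mat) {
  if (nrow(mat) < 3L) analysis_error("need >= 3 genes for tissue correlation")
  constant <- colnames(mat)[apply(mat, 2L, function(x) length(unique(x)) == 1L)]
  cm <- suppressWarnings(stats::cor(mat, method = "spearman"))
  diag(cm) <- 1
  off <- cm[upper.tri(cm)]
  off <- off[!is.na(off)]
  list(matrix = cm,
       mean_offdiag = if (length(off)) mean(off) else NA_real_,
       range_offdiag = if (length(off)) range(off) else c(NA_real_, NA_real_),
       constant_tissues = constant)
}

#' Top tissue-specific genes by expression in their top tissue
#'
#' Restricts to genes classified `specific_tau_tsi`, ranks them by the
#' expression level in their top tissue (descending, ties broken by gene
#' symbol) and reports the per-gene mean and SD of expression across all
#' tissues.
#'
#' @param scores data.frame from [score_matrix()].
#' @param labels data.frame from [classify_specific()].
#' @param mat The expression matrix the scores came from.
#' @param n Number of genes to return (default 20). If fewer are eligible,
#'   all are returned and the result carries attribute `short = TRUE`.
#' @return data.frame gene, top_tissue, top_tpm, mean_tpm, sd_tpm.
#' @export
top_specific_genes <- function(scores, labels, mat, n = 20L) {
  eligible <- labels$gene[labels$label == "specific_tau_tsi"]
  sub <- scores[scores$gene %in% eligible, , drop = FALSE]
  ord <- order(-sub$top_tpm, sub$gene, method = "radix")
  sub <- sub[ord, , drop = FALSE]
  short <- nrow(sub) < n
  sub <- utils::head(sub, n)
  out <- data.frame(gene = sub$gene,
                    top_tissue = sub$top_tissue,
                    top_tpm = sub$top_tpm,
                    mean_tpm = if (nrow(sub)) rowMeans(mat[sub$gene, , drop = FALSE]) else numeric(0),
                    sd_tpm = if (nrow(sub)) apply(mat[sub$gene, , drop = FALSE], 1L, stats::sd) else numeric(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}
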