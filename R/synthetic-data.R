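# Synthetic-data generators with planted, recoverable structure.
#
# Every generator is a pure function of (config, arguments): the RNG state is
# derived from config$seed plus a per-generator key and restored afterwards,
# so repeated calls with the same config give identical output.

#' Simulation configuration
#'
#' Assembles and validates the parameters steering all synthetic generators.
#' Defaults emulate the statistical structure of a curated cytokine catalog
#' analyzed against GTEx-style median-TPM expression (54 tissues) and
#' GWAS-catalog-style association data, at desk scale.
#'
#' @param seed Integer master seed; all generators derive child seeds from it.
#' @param n_genes Number of genes in the synthetic catalog/matrix.
#' @param n_tissues Number of tissues (>= 2).
#' @param frac_specific Fraction of genes planted as tissue-specific.
#' @param specificity_strength Ratio (>= 1) of a specific gene's top-tissue
#'   TPM to its background mean.
#' @param baseline_tpm Positive median-TPM scale of background expression.
#' @param expr_sdlog Log-normal sdlog of multiplicative expression noise
#'   (within a gene, across tissues).
#' @param gene_sdlog Log-normal sdlog of per-gene baseline levels (across
#'   genes); shared by all tissues of a gene, it induces the strong
#'   positive inter-tissue expression correlation seen in median-TPM data
#'   without affecting the scale-invariant specificity metrics.
#' @param n_clusters Number of physical gene clusters planted in the catalog.
#' @param genes_per_cluster Genes per planted cluster (>= 2).
#' @param n_eqtl_snps Number of shared (cluster) eQTL SNPs.
#' @param p_bidirectional Per shared gene-pair effect, probability that the
#'   two NES signs are opposite.
#' @param tissue_sharing Probability that an eQTL effect is replicated into
#'   any given additional tissue (same sign).
#' @param eqtl_rate_specific,eqtl_rate_other Poisson means of per-gene
#'   background eSNP counts for planted-specific and other genes; setting
#'   the first below the second plants the inverse specificity/regulation
#'   dependence.
#' @param q_threshold Significance threshold; generated p-values lie in
#'   (0, q_threshold\] with decreasing density f(p) proportional to
#'   p^(-1/2) (p = q_threshold * U^2, U uniform).
#' @param populations Named integer vector of index-SNP counts per
#'   population (names from EUR, ASN, AFR, AMR, MIXED, UNKNOWN).
#' @param ld_per_index Poisson mean of LD partners per index SNP in the four
#'   named populations.
#' @param ld_frac_high Fraction of emitted LD partner r-squared values drawn
#'   above 0.8 (the proxy threshold); the rest fall below it.
#' @param frac_esnp Fraction of index SNPs drawn from the supplied eSNP pool.
#' @param frac_selection Per index SNP, probability of a planted positive-
#'   selection signal (rank score > 2).
#' @param frac_selection_measurement Probability that an association of a
#'   selection SNP is measurement-typed.
#' @param measurement_background Same probability for non-selection SNPs.
#' @param assoc_rate Poisson mean of extra associations per index SNP (each
#'   SNP gets at least one).
#' @param functional_shift Mean advantage of index over LD SNP functional
#'   scores (score SD is 2).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       n_tissues = 54L,
                       frac_specific = 0.82,
                       specificity_strength = 50,
                       baseline_tpm = 5,
                       expr_sdlog = 0.5,
                       gene_sdlog = 1.0,
                       n_clusters = 10L,
                       genes_per_cluster = 4L,
                       n_eqtl_snps = 400L,
                       p_bidirectional = 0.35,
                       tissue_sharing = 0.15,
                       eqtl_rate_specific = 4,
                       eqtl_rate_other = 9,
                       q_threshold = 1e-4,
                       populations = c(EUR = 120L, ASN = 40L, AFR = 20L,
                                       AMR = 20L, MIXED = 15L, UNKNOWN = 10L),
                       ld_per_index = 3,
                       ld_frac_high = 0.7,
                       frac_esnp = 0.65,
                       frac_selection = 0.13,
                       frac_selection_measurement = 0.851,
                       measurement_background = 0.703,
                       assoc_rate = 0.75,
                       functional_shift = 2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              frac_specific = frac_specific,
              specificity_strength = specificity_strength,
              baseline_tpm = baseline_tpm, expr_sdlog = expr_sdlog,
              gene_sdlog = gene_sdlog,
              n_clusters = as.integer(n_clusters),
              genes_per_cluster = as.integer(genes_per_cluster),
              n_eqtl_snps = as.integer(n_eqtl_snps),
              p_bidirectional = p_bidirectional,
              tissue_sharing = tissue_sharing,
              eqtl_rate_specific = eqtl_rate_specific,
              eqtl_rate_other = eqtl_rate_other,
              q_threshold = q_threshold,
              populations = populations,
              ld_per_index = ld_per_index, ld_frac_high = ld_frac_high,
              frac_esnp = frac_esnp, frac_selection = frac_selection,
              frac_selection_measurement = frac_selection_measurement,
              measurement_background = measurement_background,
              assoc_rate = assoc_rate, functional_shift = functional_shift)
  probs <- c("frac_specific", "p_bidirectional", "tissue_sharing",
             "ld_frac_high", "frac_esnp", "frac_selection",
             "frac_selection_measurement", "measurement_background")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      config_error(sprintf("%s must be in [0, 1]", p))
    }
  }
  if (cfg$n_tissues < 2L) config_error("n_tissues must be >= 2")
  for (cnt in c("n_genes", "n_clusters", "n_eqtl_snps")) {
    if (cfg[[cnt]] < 0L) config_error(sprintf("%s must be non-negative", cnt))
  }
  if (cfg$n_genes < 1L) config_error("n_genes must be positive")
  if (cfg$genes_per_cluster < 2L) config_error("genes_per_cluster must be >= 2")
  if (cfg$specificity_strength < 1) {
    config_error("specificity_strength must be >= 1")
  }
  if (cfg$baseline_tpm <= 0) config_error("baseline_tpm must be positive")
  if (cfg$gene_sdlog < 0) config_error("gene_sdlog must be non-negative")
  if (is.null(names(cfg$populations)) ||
      any(!names(cfg$populations) %in% cyto_vocab$gwas_population)) {
    config_error("populations must be named with known population codes")
  }
  structure(cfg, class = "sim_config")
}

.sim_tissues <- function(config) sprintf("T%02d", seq_len(config$n_tissues))
.sim_genes <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Generate a synthetic gene catalog with planted physical clusters
#'
#' The first `n_clusters * genes_per_cluster` genes are laid out in tight
#' clusters (consecutive genes ~50 kb apart) spread over chromosomes; the
#' remaining genes are isolated (10 Mb apart) so they never chain into
#' clusters. Activity classes are sampled from the closed vocabulary.
#'
#' @param config A [sim_config()].
#' @return data.frame in the `gene_catalog` schema (with `cluster_id` set
#'   for clustered genes).
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_clustered <- config$n_clusters * config$genes_per_cluster
  if (n_clustered > config$n_genes) {
    config_error("n_clusters * genes_per_cluster exceeds n_genes")
  }
  with_seed(child_seed(config$seed, "catalog"), {
    genes <- .sim_genes(config)
    chrom <- character(config$n_genes)
    start <- numeric(config$n_genes)
    end <- numeric(config$n_genes)
    cluster_id <- rep(NA_character_, config$n_genes)
    i <- 1L
    for (k in seq_len(config$n_clusters)) {
      ch <- paste0("chr", ((k - 1L) %% 22L) + 1L)
      pos <- 1e6 + ((k - 1L) %/% 22L) * 5e7
      for (g in seq_len(config$genes_per_cluster)) {
        len <- round(stats::runif(1, 1e4, 8e4))
        chrom[i] <- ch
        start[i] <- pos
        end[i] <- pos + len
        cluster_id[i] <- sprintf("C%02d", k)
        pos <- pos + len + round(stats::runif(1, 2e4, 8e4))
        i <- i + 1L
      }
    }
    j <- 0L
    while (i <= config$n_genes) {
      ch <- paste0("chr", (j %% 22L) + 1L)
      pos <- 1.2e8 + (j %/% 22L) * 1e7
      len <- round(stats::runif(1, 1e4, 8e4))
      chrom[i] <- ch
      start[i] <- pos
      end[i] <- pos + len
      i <- i + 1L
      j <- j + 1L
    }
    classes <- sample(cyto_vocab$activity_classes, config$n_genes,
                      replace = TRUE)
    validate_records(
      data.frame(symbol = genes, chromosome = chrom, start = start, end = end,
                 activity_classes = I(as.list(classes)),
                 cluster_id = cluster_id, stringsAsFactors = FALSE),
      "gene_catalog")
  })
}

#' Generate a synthetic median-TPM expression matrix with planted specificity
#'
#' A planted fraction of genes is tissue-specific: one randomly chosen top
#' tissue carries `specificity_strength` times the gene's background mean,
#' under multiplicative log-normal noise. All other values are i.i.d.
#' log-normal around `baseline_tpm`.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (gene-by-tissue, non-negative) and `truth`
#'   (data.frame gene, is_specific, top_tissue).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2L) config_error("n_tissues must be >= 2")
  with_seed(child_seed(config$seed, "expression"), {
    genes <- .sim_genes(config)
    tissues <- .sim_tissues(config)
    n_spec <- round(config$frac_specific * config$n_genes)
    spec_idx <- sample(config$n_genes, n_spec)
    is_specific <- seq_len(config$n_genes) %in% spec_idx
    gene_level <- stats::rlnorm(config$n_genes,
                                meanlog = log(config$baseline_tpm),
                                sdlog = config$gene_sdlog)
    mat <- gene_level * matrix(stats::rlnorm(config$n_genes * config$n_tissues,
                                             meanlog = 0,
                                             sdlog = config$expr_sdlog),
                               nrow = config$n_genes,
                               dimnames = list(genes, tissues))
    top_tissue <- rep(NA_character_, config$n_genes)
    for (i in spec_idx) {
      j <- sample.int(config$n_tissues, 1L)
      mat[i, j] <- config$specificity_strength * mean(mat[i, -j]) *
        stats::rlnorm(1, 0, config$expr_sdlog)
      top_tissue[i] <- tissues[j]
    }
    list(matrix = mat,
         truth = data.frame(gene = genes, is_specific = is_specific,
                            top_tissue = top_tissue,
                            stringsAsFactors = FALSE))
  })
}

.rp_sig <- function(n, q_threshold) q_threshold * stats::runif(n)^2

#' Generate significant cis-eQTL associations with planted effect directions
#'
#' Two layers are emitted. (1) Shared cluster effects: each of `n_eqtl_snps`
#' SNPs lands in a planted cluster, hits a random gene pair in one base
#' tissue with opposite NES signs with probability `p_bidirectional` (same
#' signs otherwise), and is replicated into each additional tissue with
#' probability `tissue_sharing`, preserving signs. (2) Per-gene background
#' eSNPs: Poisson counts with mean `eqtl_rate_specific` for genes named in
#' `specific_genes` and `eqtl_rate_other` for the rest, planting an inverse
#' specificity/eQTL-count dependence. NES magnitudes are log-normal; all
#' p-values are drawn from the decreasing density f(p) ~ p^(-1/2) on
#' (0, q_threshold\] (only significant pairs are generated).
#'
#' @param config A [sim_config()].
#' @param genes Gene catalog data.frame (from [gen_catalog()] or
#'   [read_table()]); clustered genes must carry coordinates.
#' @param specific_genes Optional character vector of planted-specific gene
#'   symbols (e.g. from [gen_expression()] truth) steering background rates.
#' @return List with `eqtl` (data.frame in the `eqtl` schema) and `truth`
#'   (data.frame snp_id, cluster_id, gene_a, gene_b, base_tissue,
#'   bidirectional, n_tissues).
#' @export
gen_eqtl <- function(config, genes, specific_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  clustered <- genes[!is.na(genes$cluster_id), , drop = FALSE]
  if (config$n_clusters > 0L && nrow(clustered) == 0L) {
    config_error("catalog has no clustered genes but n_clusters > 0")
  }
  with_seed(child_seed(config$seed, "eqtl"), {
    tissues <- .sim_tissues(config)
    cl_ids <- unique(clustered$cluster_id)
    rec <- list()
    truth <- list()
    emit <- function(snp, chrom, pos, gene, tissue, nes) {
      data.frame(snp_id = snp, chromosome = chrom, position = pos,
                 gene = gene, tissue = tissue, nes = nes,
                 pval = .rp_sig(length(tissue), config$q_threshold),
                 stringsAsFactors = FALSE)
    }
    if (length(cl_ids) > 0L && config$n_eqtl_snps > 0L) {
      cl_of_snp <- sample(cl_ids, config$n_eqtl_snps, replace = TRUE)
      for (s in seq_len(config$n_eqtl_snps)) {
        members <- clustered[clustered$cluster_id == cl_of_snp[s], ,
                             drop = FALSE]
        pair <- members[sample(nrow(members), 2L), , drop = FALSE]
        snp <- sprintf("rsS%05d", s)
        pos <- round(mean(c(pair$start, pair$end)) +
                       stats::runif(1, -2e5, 2e5))
        sign_a <- sample(c(-1, 1), 1L)
        bidir <- stats::runif(1) < config$p_bidirectional
        sign_b <- if (bidir) -sign_a else sign_a
        tis <- tissues[sample.int(config$n_tissues, 1L)]
        extra <- setdiff(tissues, tis)
        tis <- c(tis, extra[stats::runif(length(extra)) < config$tissue_sharing])
        k <- length(tis)
        mag <- function() stats::rlnorm(k, log(0.3), 0.5)
        rec[[length(rec) + 1L]] <-
          rbind(emit(snp, pair$chromosome[1L], pos, pair$symbol[1L], tis,
                     sign_a * mag()),
                emit(snp, pair$chromosome[1L], pos, pair$symbol[2L], tis,
                     sign_b * mag()))
        ga <- sort(pair$symbol)
        truth[[length(truth) + 1L]] <-
          data.frame(snp_id = snp, cluster_id = cl_of_snp[s],
                     gene_a = ga[1L], gene_b = ga[2L], base_tissue = tis[1L],
                     bidirectional = bidir, n_tissues = k,
                     stringsAsFactors = FALSE)
      }
    }
    # background (non-shared) eSNPs steering per-gene eQTL counts
    b <- 0L
    for (i in seq_len(nrow(genes))) {
      rate <- if (!is.null(specific_genes) &&
                  genes$symbol[i] %in% specific_genes) {
        config$eqtl_rate_specific
      } else config$eqtl_rate_other
      n_bg <- stats::rpois(1L, rate)
      if (n_bg == 0L) next
      for (s in seq_len(n_bg)) {
        b <- b + 1L
        snp <- sprintf("rsB%06d", b)
        base0 <- if (is.na(genes$start[i])) 1e6 else genes$start[i]
        pos <- round(base0 + stats::runif(1, -5e5, 5e5))
        tis <- tissues[sample.int(config$n_tissues, 1L)]
        extra <- setdiff(tissues, tis)
        tis <- c(tis, extra[stats::runif(length(extra)) < config$tissue_sharing])
        sgn <- sample(c(-1, 1), 1L)
        rec[[length(rec) + 1L]] <-
          emit(snp, if (is.na(genes$chromosome[i])) "chr1" else genes$chromosome[i],
               max(pos, 1), genes$symbol[i], tis,
               sgn * stats::rlnorm(length(tis), log(0.3), 0.5))
      }
    }
    eqtl <- if (length(rec)) do.call(rbind, rec) else
      data.frame(snp_id = character(0), chromosome = character(0),
                 position = numeric(0), gene = character(0),
                 tissue = character(0), nes = numeric(0), pval = numeric(0))
    rownames(eqtl) <- NULL
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(snp_id = character(0), cluster_id = character(0),
                 gene_a = character(0), gene_b = character(0),
                 base_tissue = character(0), bidirectional = logical(0),
                 n_tissues = integer(0))
    list(eqtl = validate_records(eqtl, "eqtl"), truth = truth)
  })
}

#' Generate GWAS-catalog-style tables with planted LD, selection and scores
#'
#' Index SNPs are assigned to populations per `config$populations`; a
#' configurable fraction is drawn from the supplied eSNP pool (the rest are
#' novel, planting the eSNP/non-eSNP partition). Index SNPs in the four
#' named populations receive Poisson-many LD partners, whose r-squared
#' values exceed 0.8 with probability `ld_frac_high`. A planted fraction of
#' index SNPs carries a positive-selection signal (rank score > 2 and an
#' absolute score above the statistic's conventional cutoff: Fst >= 0.5,
#' |iHS| >= 2). Associations of selection SNPs are measurement-typed with
#' probability `frac_selection_measurement`, others with
#' `measurement_background`. Functional scores of index SNPs are normal with
#' mean `functional_shift` (SD 2) versus mean 0 for LD SNPs, i.e.
#' stochastically larger.
#'
#' @param config A [sim_config()].
#' @param snps Character vector of eSNP identifiers to draw index SNPs from.
#' @param genes Optional gene symbols for `mapped_genes`.
#' @return List with data.frames `gwas`, `ld`, `selection`,
#'   `snp_annotation`, and `truth` (per-SNP planted role, population,
#'   esnp/selection status).
#' @export
gen_gwas <- function(config, snps, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "gwas"), {
    pops <- config$populations
    n_index <- sum(pops)
    population <- rep(names(pops), times = pops)
    n_from_pool <- min(round(config$frac_esnp * n_index), length(snps))
    pool <- if (n_from_pool > 0L) sample(snps, n_from_pool) else character(0)
    novel <- sprintf("rsG%05d", seq_len(n_index - n_from_pool))
    snp_id <- sample(c(pool, novel))  # shuffle pool/novel across populations
    is_esnp_planted <- snp_id %in% pool
    is_selected <- stats::runif(n_index) < config$frac_selection

    # selection scores: one record per index SNP
    statistic <- sample(cyto_vocab$selection_statistic, n_index, replace = TRUE)
    is_fst <- grepl("^fst", statistic)
    rank_score <- ifelse(is_selected, 2 + stats::rexp(n_index, 1),
                         stats::runif(n_index, 0, 2))
    abs_score <- ifelse(is_selected,
                        ifelse(is_fst, stats::runif(n_index, 0.5, 0.75),
                               stats::runif(n_index, 2, 4.6)),
                        ifelse(is_fst, stats::runif(n_index, 0, 0.45),
                               stats::runif(n_index, 0, 1.9)))
    selection <- data.frame(snp_id = snp_id, statistic = statistic,
                            abs_score = abs_score, rank_score = rank_score,
                            stringsAsFactors = FALSE)

    # LD partners for the four reference populations only
    ld_rows <- list()
    ld_snps <- character(0)
    eligible <- which(population %in% cyto_vocab$ld_population)
    for (i in eligible) {
      n_p <- stats::rpois(1L, config$ld_per_index)
      if (n_p == 0L) next
      partners <- sprintf("rsL%05d_%d", i, seq_len(n_p))
      high <- stats::runif(n_p) < config$ld_frac_high
      r2 <- ifelse(high, stats::runif(n_p, 0.8, 1), stats::runif(n_p, 0.1, 0.8))
      a <- pmin(snp_id[i], partners)
      bb <- pmax(snp_id[i], partners)
      ld_rows[[length(ld_rows) + 1L]] <-
        data.frame(snp_a = a, snp_b = bb, population = population[i],
                   r2 = r2, stringsAsFactors = FALSE)
      ld_snps <- c(ld_snps, partners[r2 > 0.8])
    }
    ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else
      data.frame(snp_a = character(0), snp_b = character(0),
                 population = character(0), r2 = numeric(0))

    # GWAS associations (>= 1 per index SNP)
    gene_pool <- genes %||% sprintf("G%04d", seq_len(max(config$n_genes, 1L)))
    meas_types <- c("anthropometric measurement", "protein measurement",
                    "inflammatory biomarker measurement")
    # region classes planted: eSNPs enriched in regulatory/intronic regions
    reg_esnp <- c(intronic = 0.40, missense = 0.04, synonymous = 0.03,
                  utr3 = 0.05, utr5 = 0.04, intergenic_regulatory = 0.30,
                  intergenic_other = 0.06, other_intragenic = 0.08)
    reg_other <- c(intronic = 0.25, missense = 0.04, synonymous = 0.03,
                   utr3 = 0.04, utr5 = 0.03, intergenic_regulatory = 0.08,
                   intergenic_other = 0.45, other_intragenic = 0.08)
    gw <- list()
    for (i in seq_len(n_index)) {
      n_a <- 1L + stats::rpois(1L, config$assoc_rate)
      p_meas <- if (is_selected[i]) config$frac_selection_measurement else
        config$measurement_background
      is_meas <- stats::runif(n_a) < p_meas
      w <- if (is_esnp_planted[i]) reg_esnp else reg_other
      region <- sample(names(w), 1L, prob = w)
      mg <- paste(sample(gene_pool, sample(1:2, 1L)), collapse = ",")
      gw[[i]] <- data.frame(
        snp_id = snp_id[i],
        mapped_genes = mg,
        trait = ifelse(is_meas,
                       sample(meas_types, n_a, replace = TRUE),
                       sprintf("disease_%02d", sample.int(30L, n_a,
                                                          replace = TRUE))),
        disease_type = ifelse(is_meas, "", "inflammatory disease"),
        anatomical_system = ifelse(is_meas, "", "immune system"),
        measurement_type = ifelse(is_meas,
                                  sample(meas_types, n_a, replace = TRUE), ""),
        disease = ifelse(is_meas, "", sprintf("disease_%02d",
                                              sample.int(30L, n_a,
                                                         replace = TRUE))),
        population = population[i],
        region_class = region,
        stringsAsFactors = FALSE)
    }
    gwas <- do.call(rbind, gw)
    rownames(gwas) <- NULL

    ld_snps <- unique(ld_snps)
    annot <- data.frame(
      snp_id = c(snp_id, ld_snps),
      role = c(rep("index", n_index), rep("ld", length(ld_snps))),
      functional_score = c(stats::rnorm(n_index, config$functional_shift, 2),
                           stats::rnorm(length(ld_snps), 0, 2)),
      stringsAsFactors = FALSE)

    truth <- data.frame(snp_id = snp_id, population = population,
                        is_esnp = is_esnp_planted, is_selected = is_selected,
                        stringsAsFactors = FALSE)
    list(gwas = validate_records(gwas, "gwas"),
         ld = validate_records(ld, "ld"),
         selection = validate_records(selection, "selection"),
         snp_annotation = validate_records(annot, "snp_annotation"),
         truth = truth)
  })
}
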