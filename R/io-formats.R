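# Readers/writers for the pipeline's tabular formats.
#
# Conventions (all file-level docs inherit these):
#   * coordinates are 1-based inclusive base pairs, GRCh38;
#   * gene identity is by symbol;
#   * TSV = tab-separated, UTF-8, header row; GCT 1.2 only for expression.

#' Closed vocabularies used by the table schemas
#'
#' @format Named list of character vectors.
#' @keywords internal
cyto_vocab <- list(
  activity_classes = c("cytokine_activity", "chemokine_activity",
                       "cytokine_receptor_activity",
                       "chemokine_receptor_activity",
                       "growth_factor_activity"),
  gwas_population  = c("EUR", "ASN", "AFR", "AMR", "MIXED", "UNKNOWN"),
  ld_population    = c("EUR", "ASN", "AFR", "AMR"),
  region_class     = c("intronic", "missense", "synonymous", "utr3", "utr5",
                       "intergenic_regulatory", "intergenic_other",
                       "other_intragenic"),
  selection_statistic = c("fst_global", "fst_ceu_chb", "fst_ceu_yri",
                          "ihs_ceu", "ihs_chb", "ihs_yri"),
  snp_role         = c("index", "ld")
)

.schema_columns <- list(
  gene_catalog   = c("symbol", "chromosome", "start", "end",
                     "activity_classes", "cluster_id"),
  eqtl           = c("snp_id", "chromosome", "position", "gene", "tissue",
                     "nes", "pval"),
  gwas           = c("snp_id", "mapped_genes", "trait", "disease_type",
                     "anatomical_system", "measurement_type", "disease",
                     "population", "region_class"),
  ld             = c("snp_a", "snp_b", "population", "r2"),
  selection      = c("snp_id", "statistic", "abs_score", "rank_score"),
  snp_annotation = c("snp_id", "role", "functional_score")
)

.split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0)
    else trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
  })
}

.collapse_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), character(1))
}

.row_fail <- function(rows, msg) {
  validation_error(sprintf("row %s: %s", paste(rows, collapse = ", "), msg))
}

#' Read a GCT 1.2 expression matrix of median TPM values
#'
#' Parses the GCT 1.2 dialect (`#1.2` version line, a `rows<TAB>cols` line,
#' then a `Name`/`Description` header followed by one row per gene). Values
#' are median TPM and must be non-negative; gene symbols must be unique.
#'
#' @param path Path to a GCT file.
#' @return Numeric matrix, genes in rows (rownames = symbols), tissues in
#'   columns (colnames = tissue names).
#' @seealso [write_expression_gct()]
#' @export
read_expression_gct <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
    format_error("malformed GCT: first line must be '#1.2'")
  }
  dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  nr <- suppressWarnings(as.integer(dims[1L]))
  nc <- suppressWarnings(as.integer(dims[2L]))
  if (length(dims) < 2L || is.na(nr) || is.na(nc)) {
    format_error("malformed GCT: second line must declare '<rows>\\t<cols>'")
  }
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != nc + 2L) {
    format_error(sprintf(
      "GCT dimension mismatch: header declares %d data columns, expected %d",
      length(header) - 2L, nc))
  }
  tissues <- header[-(1:2)]
  if (anyDuplicated(tissues)) {
    validation_error("duplicate tissue names in GCT header")
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    format_error(sprintf("GCT dimension mismatch: declared %d rows, found %d",
                         nr, length(body)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != nc + 2L)
  if (length(bad) > 0L) {
    format_error(sprintf("GCT dimension mismatch on body row %d", bad[1L]))
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    validation_error(sprintf("duplicate gene symbol(s): %s",
                             paste(unique(genes[duplicated(genes)]),
                                   collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-(1:2)]), numeric(nc)))
  mat <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat)) format_error("GCT contains non-numeric expression values")
  if (any(mat < 0)) {
    validation_error(sprintf("negative expression value on body row %d",
                             which(apply(mat < 0, 1L, any))[1L]))
  }
  dimnames(mat) <- list(genes, tissues)
  mat
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @param mat Numeric gene-by-tissue matrix with dimnames.
#' @param path Output path.
#' @param descriptions Optional per-gene description column (defaults to
#'   the gene symbol).
#' @return `path`, invisibly.
#' @export
write_expression_gct <- function(mat, path, descriptions = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(mat < 0)) validation_error("negative expression value")
  desc <- descriptions %||% rownames(mat)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t"),
               paste(c("Name", "Description", colnames(mat)), collapse = "\t")),
             con)
  body <- apply(format(mat, trim = TRUE, digits = 15, scientific = FALSE),
                1L, paste, collapse = "\t")
  writeLines(paste(rownames(mat), desc, body, sep = "\t"), con)
  invisible(path)
}

#' Read and validate a typed pipeline table
#'
#' Reads a TSV and enforces the invariants of one of the six record schemas.
#' Multi-valued columns (`activity_classes`, `mapped_genes` and the four EFO
#' category columns of the `gwas` schema) are comma-separated in the file and
#' returned as list columns. Unknown extra columns are preserved. Every
#' invariant violation is reported with the offending (1-based, header
#' excluded) row number.
#'
#' Schemas:
#' \describe{
#'   \item{gene_catalog}{symbol, chromosome, start, end, activity_classes,
#'     cluster_id. Symbols unique; activity classes a non-empty subset of the
#'     closed vocabulary; start <= end where coordinates are present
#'     (coordinates may be missing, such genes are skipped by
#'     position-dependent steps).}
#'   \item{eqtl}{snp_id, chromosome, position, gene, tissue, nes, pval.
#'     nes nonzero; pval in (0, 1].}
#'   \item{gwas}{snp_id, mapped_genes, trait, disease_type,
#'     anatomical_system, measurement_type, disease, population,
#'     region_class. population and region_class from closed vocabularies.}
#'   \item{ld}{snp_a, snp_b, population, r2 in \[0, 1\]. Pairs are
#'     canonicalized so snp_a < snp_b; duplicated (pair, population) rows are
#'     rejected.}
#'   \item{selection}{snp_id, statistic, abs_score, rank_score >= 0;
#'     statistic from the closed vocabulary.}
#'   \item{snp_annotation}{snp_id, role in \{index, ld\}, functional_score
#'     (may be missing); extra columns carried through.}
#' }
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"gene_catalog"`, `"eqtl"`, `"gwas"`, `"ld"`,
#'   `"selection"`, `"snp_annotation"`.
#' @return A validated data.frame of typed records.
#' @export
read_table <- function(path, schema = names(.schema_columns)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"),
                          colClasses = "character")
  stopifnot_cols(df, .schema_columns[[schema]], sprintf("schema '%s'", schema))
  validate_records(df, schema)
}

.as_num <- function(df, col, what) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (length(bad) > 0L) .row_fail(bad[1L], sprintf("%s is not numeric", what))
  x
}

#' Validate a data.frame against a record schema
#'
#' The in-memory counterpart of [read_table()]: applies the same invariant
#' checks and type coercions to an already-loaded data.frame.
#'
#' @param df A data.frame with the schema's columns (character or typed).
#' @param schema Schema name, as in [read_table()].
#' @return The validated, typed data.frame.
#' @export
validate_records <- function(df, schema = names(.schema_columns)) {
  schema <- match.arg(schema)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (schema == "gene_catalog") {
    if (!is.list(df$activity_classes)) {
      df$activity_classes <- .split_multi(as.character(df$activity_classes))
    }
    empty <- which(lengths(df$activity_classes) == 0L)
    if (length(empty) > 0L) .row_fail(empty[1L], "activity_classes is empty")
    unknown <- which(vapply(df$activity_classes, function(a) {
      any(!a %in% cyto_vocab$activity_classes)
    }, logical(1)))
    if (length(unknown) > 0L) {
      .row_fail(unknown[1L], "unknown activity class")
    }
    dup <- which(duplicated(df$symbol))
    if (length(dup) > 0L) {
      .row_fail(dup[1L], sprintf("duplicate gene symbol '%s'",
                                 df$symbol[dup[1L]]))
    }
    df$start <- .as_num(df, "start", "start")
    df$end <- .as_num(df, "end", "end")
    bad <- which(!is.na(df$start) & !is.na(df$end) & df$start > df$end)
    if (length(bad) > 0L) .row_fail(bad[1L], "start > end")
  } else if (schema == "eqtl") {
    df$position <- .as_num(df, "position", "position")
    df$nes <- .as_num(df, "nes", "nes")
    df$pval <- .as_num(df, "pval", "pval")
    bad <- which(is.na(df$nes) | df$nes == 0)
    if (length(bad) > 0L) .row_fail(bad[1L], "nes must be nonzero")
    bad <- which(is.na(df$pval) | df$pval <= 0 | df$pval > 1)
    if (length(bad) > 0L) .row_fail(bad[1L], "pval must be in (0, 1]")
  } else if (schema == "gwas") {
    for (col in c("mapped_genes", "disease_type", "anatomical_system",
                  "measurement_type", "disease")) {
      if (!is.list(df[[col]])) df[[col]] <- .split_multi(as.character(df[[col]]))
    }
    bad <- which(!df$population %in% cyto_vocab$gwas_population)
    if (length(bad) > 0L) {
      .row_fail(bad[1L], sprintf("population '%s' not in closed vocabulary",
                                 df$population[bad[1L]]))
    }
    bad <- which(!df$region_class %in% cyto_vocab$region_class)
    if (length(bad) > 0L) {
      .row_fail(bad[1L], sprintf("region_class '%s' not in closed vocabulary",
                                 df$region_class[bad[1L]]))
    }
  } else if (schema == "ld") {
    df$r2 <- .as_num(df, "r2", "r2")
    bad <- which(is.na(df$r2) | df$r2 < 0 | df$r2 > 1)
    if (length(bad) > 0L) .row_fail(bad[1L], "r2 must be in [0, 1]")
    bad <- which(!df$population %in% cyto_vocab$ld_population)
    if (length(bad) > 0L) {
      .row_fail(bad[1L], sprintf("population '%s' not in closed vocabulary",
                                 df$population[bad[1L]]))
    }
    # canonical unordered pair: snp_a lexicographically first
    swap <- df$snp_a > df$snp_b
    if (any(swap)) {
      tmp <- df$snp_a[swap]
      df$snp_a[swap] <- df$snp_b[swap]
      df$snp_b[swap] <- tmp
    }
    key <- paste(df$snp_a, df$snp_b, df$population, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      .row_fail(dup[1L], "duplicate unordered (snp_a, snp_b) pair for population")
    }
  } else if (schema == "selection") {
    df$abs_score <- .as_num(df, "abs_score", "abs_score")
    df$rank_score <- .as_num(df, "rank_score", "rank_score")
    bad <- which(!df$statistic %in% cyto_vocab$selection_statistic)
    if (length(bad) > 0L) {
      .row_fail(bad[1L], sprintf("statistic '%s' not in closed vocabulary",
                                 df$statistic[bad[1L]]))
    }
    bad <- which(is.na(df$rank_score) | df$rank_score < 0)
    if (length(bad) > 0L) .row_fail(bad[1L], "rank_score must be >= 0")
  } else if (schema == "snp_annotation") {
    bad <- which(!df$role %in% cyto_vocab$snp_role)
    if (length(bad) > 0L) {
      .row_fail(bad[1L], sprintf("role '%s' not in {index, ld}",
                                 df$role[bad[1L]]))
    }
    df$functional_score <- .as_num(df, "functional_score", "functional_score")
  }
  rownames(df) <- NULL
  df
}

#' Write result tables deterministically and emit a manifest
#'
#' Writes each table as a TSV with a fixed column order (as supplied) and a
#' deterministic row sort (lexicographic over all columns rendered as text),
#' so that two runs with identical inputs and configuration produce
#' byte-identical files. A `manifest.json` records file names, row counts and
#' an MD5 digest of the run configuration.
#'
#' @param tables Named list of data.frames (may be empty).
#' @param out_dir Output directory, created if absent.
#' @param config Optional configuration object recorded via its digest.
#' @return The manifest (named list), invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (length(tables) > 0L &&
      (is.null(names(tables)) || any(!nzchar(names(tables))))) {
    validation_error("'tables' must be a fully named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2L) != 0L) {
    cyto_error(sprintf("output directory not writable: %s", out_dir),
               "cytomap_io_error")
  }
  digest <- .config_digest(config)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]], stringsAsFactors = FALSE)
    for (col in names(df)) {
      if (is.list(df[[col]])) df[[col]] <- .collapse_multi(df[[col]])
    }
    if (nrow(df) > 1L) {
      keys <- lapply(df, function(x) format(x, trim = TRUE, digits = 15))
      df <- df[do.call(order, c(keys, list(method = "radix"))), , drop = FALSE]
    }
    fn <- paste0(nm, ".tsv")
    utils::write.table(df, file.path(out_dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <- c(files, fn)
    rows <- c(rows, nrow(df))
  }
  manifest <- list(files = as.list(files),
                   rows = stats::setNames(as.list(rows), files),
                   config_digest = digest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}
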