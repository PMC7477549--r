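# Internal helpers: classed conditions and deterministic child seeds.

cyto_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cytomap_error", "error")))
}

format_error     <- function(msg) cyto_error(msg, "cytomap_format_error")
validation_error <- function(msg) cyto_error(msg, "cytomap_validation_error")
config_error     <- function(msg) cyto_error(msg, "cytomap_config_error")
analysis_error   <- function(msg) cyto_error(msg, "cytomap_analysis_error")

#' @keywords internal
#' @noRd
stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    cyto_error(sprintf("%s: missing required column(s): %s",
                       what, paste(missing, collapse = ", ")),
               "cytomap_schema_error")
  }
}

# Deterministic child seed from a parent seed and a string key, kept inside
# the 32-bit signed integer range so set.seed() accepts it everywhere.
child_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Run an expression with a locally-set RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
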