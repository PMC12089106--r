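# Internal helpers: classed conditions, seeded evaluation, TSV plumbing.

cn_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cnseq_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_argument <- function(msg) cn_abort(msg, "cnseq_argument_error")
abort_validation <- function(msg) cn_abort(msg, "cnseq_validation_error")
abort_parse <- function(msg) cn_abort(msg, "cnseq_parse_error")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_argument("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# per-stage streams. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% .Machine$integer.max
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)
}
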