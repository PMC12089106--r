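#' Construct a validated FPKM expression matrix
#'
#' An `ExpressionMatrix` is a numeric matrix of non-negative FPKM values
#' with genes as rows and samples as columns. Gene and sample identifiers
#' are opaque, case-sensitive strings and must be unique; missing cells are
#' rejected rather than imputed.
#'
#' @param values numeric matrix of FPKM values, genes x samples.
#' @param gene_ids character vector of row identifiers
#'   (default `rownames(values)`).
#' @param sample_ids character vector of column identifiers
#'   (default `colnames(values)`).
#' @return an object of class `ExpressionMatrix` (a classed numeric matrix).
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 0, 5, 2, 0, 1), nrow = 3,
#'                              dimnames = list(c("g1", "g2", "g3"),
#'                                              c("s1", "s2"))))
#' dim(m)
#' @export
ExpressionMatrix <- function(values, gene_ids = rownames(values),
                             sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_argument("`values` must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort_argument("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort_validation("identifier lists do not match matrix dimensions")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort_validation(sprintf("duplicate gene identifiers: %s",
                             paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort_validation(sprintf("duplicate sample identifiers: %s",
                             paste(dup_s, collapse = ", ")))
  }
  if (anyNA(values)) abort_validation("missing cells are not allowed")
  if (any(values < 0)) abort_validation("FPKM values must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(matrix()))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  n <- min(5L, nrow(x))
  m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... and %d more genes\n", nrow(x) - n))
  invisible(x)
}

gene_ids <- function(m) rownames(m)
sample_ids <- function(m) colnames(m)

#' Read an FPKM table from TSV
#'
#' Expects a header line `gene_id<TAB>sample1<TAB>...` followed by one row
#' per gene. The first column holds gene identifiers, the remaining columns
#' numeric FPKM readings. Input gene order is preserved.
#'
#' @param path path to the TSV file.
#' @param sep field separator (default tab).
#' @return an [ExpressionMatrix].
#' @export
read_fpkm_table <- function(path, sep = "\t") {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort_parse(sprintf("empty file: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) abort_parse("expected a gene_id column plus at least one sample column")
  ids <- raw[[1L]]
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L)
  for (j in seq.int(2L, ncol(raw))) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(col))
    if (length(bad)) {
      abort_parse(sprintf(
        "non-numeric or missing value at row %d, column '%s': '%s'",
        bad[1L], names(raw)[j], raw[[j]][bad[1L]]))
    }
    neg <- which(col < 0)
    if (length(neg)) {
      abort_parse(sprintf("negative value at row %d, column '%s'",
                          neg[1L], names(raw)[j]))
    }
    num[, j - 1L] <- col
  }
  ExpressionMatrix(num, gene_ids = ids, sample_ids = names(raw)[-1L])
}

#' Write an FPKM table to TSV
#'
#' Inverse of [read_fpkm_table()]; finite decimal inputs round-trip
#' bit-identically.
#'
#' @param m an [ExpressionMatrix].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fpkm_table <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(m),
                   format(unclass(m), trim = TRUE, scientific = FALSE,
                          digits = 15, drop0trailing = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", sample_ids(m))
  write_tsv(df, path)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `group`, `batch`; optional `sex` and
#' `age_years`. Group labels must lie in `groups`; batch labels in
#' `batches`, when given.
#'
#' @param path path to the metadata TSV.
#' @param groups allowed group labels.
#' @param batches allowed batch labels, or `NULL` for unconstrained.
#' @return a `data.frame` of class `SampleMetadata`.
#' @export
read_sample_metadata <- function(path, groups = c("control", "AD", "PD"),
                                 batches = c("session1", "session2")) {
  df <- read_tsv(path)
  SampleMetadata(df, groups = groups, batches = batches)
}

#' Construct sample metadata
#'
#' @param df data.frame with columns `sample_id`, `group`, `batch` and
#'   optionally `sex`, `age_years`.
#' @inheritParams read_sample_metadata
#' @return a validated `SampleMetadata` data.frame.
#' @export
SampleMetadata <- function(df, groups = c("control", "AD", "PD"),
                           batches = c("session1", "session2")) {
  need <- c("sample_id", "group", "batch")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_parse(sprintf("metadata lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$batch <- as.character(df$batch)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    abort_validation(sprintf("duplicate sample_id in metadata: %s",
                             paste(dup, collapse = ", ")))
  }
  bad_g <- setdiff(df$group, groups)
  if (length(bad_g)) {
    abort_validation(sprintf("unknown group label(s): %s (allowed: %s)",
                             paste(bad_g, collapse = ", "),
                             paste(groups, collapse = ", ")))
  }
  if (!is.null(batches)) {
    bad_b <- setdiff(df$batch, batches)
    if (length(bad_b)) {
      abort_validation(sprintf("unknown batch label(s): %s",
                               paste(bad_b, collapse = ", ")))
    }
  }
  if ("age_years" %in% names(df)) {
    df$age_years <- as.numeric(df$age_years)
    if (any(!is.na(df$age_years) & df$age_years < 0)) {
      abort_validation("age_years must be non-negative")
    }
  }
  class(df) <- c("SampleMetadata", "data.frame")
  df
}

#' Check that a matrix and metadata describe the same samples
#'
#' Every sample in the matrix must have exactly one metadata record.
#'
#' @param m an [ExpressionMatrix].
#' @param meta a `SampleMetadata` data.frame.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_samples <- function(m, meta) {
  orphans <- setdiff(sample_ids(m), meta$sample_id)
  if (length(orphans)) {
    abort_validation(sprintf("samples without metadata: %s",
                             paste(orphans, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Filter genes by detection across samples
#'
#' Retains genes with FPKM > 0 in at least `min_samples_nonzero` samples.
#' The cohort's published locus total (62,704) versus the analysed subset
#' (41,971) implies some detection filter whose rule is not public, so the
#' threshold is a parameter; `min_samples_nonzero = 0` is the identity.
#'
#' @param m an [ExpressionMatrix].
#' @param min_samples_nonzero minimum number of samples with FPKM > 0.
#' @return the filtered [ExpressionMatrix] (possibly with zero rows).
#' @export
filter_expressed <- function(m, min_samples_nonzero = 1L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is_count(min_samples_nonzero) || min_samples_nonzero > ncol(m)) {
    abort_argument("`min_samples_nonzero` must be an integer in [0, n_samples]")
  }
  keep <- rowSums(unclass(m) > 0) >= min_samples_nonzero
  ExpressionMatrix(unclass(m)[keep, , drop = FALSE],
                   gene_ids = gene_ids(m)[keep],
                   sample_ids = sample_ids(m))
}

#' Log-transform an expression matrix
#'
#' Replaces every value `v` with `log2(v + pseudocount)`. Used for PCA,
#' clustering and the enrichment ranking metric; group means and fold
#' changes are always reported on the raw FPKM scale.
#'
#' @param m an [ExpressionMatrix].
#' @param pseudocount positive offset added before taking logs.
#' @return a matrix of the same shape (plain numeric matrix, since values
#'   may be negative after the transform when `pseudocount < 1`).
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is_scalar_number(pseudocount) || pseudocount <= 0) {
    abort_argument("`pseudocount` must be a positive number")
  }
  out <- log2(unclass(m) + pseudocount)
  dimnames(out) <- dimnames(m)
  out
}

#' Read a gene panel (one identifier per line)
#'
#' @param path path to a plain-text file, one gene identifier per line;
#'   blank lines and lines starting with `#` are ignored.
#' @param name panel label (default: file name without extension).
#' @return a list with `name` and `gene_ids`, class `GenePanel`.
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort_validation("gene panel is empty")
  dup <- unique(lines[duplicated(lines)])
  if (length(dup)) {
    abort_validation(sprintf("duplicate panel identifiers: %s",
                             paste(dup, collapse = ", ")))
  }
  structure(list(name = name %||% tools::file_path_sans_ext(basename(path)),
                 gene_ids = lines),
            class = "GenePanel")
}
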