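#' Construct a chromosome-length table
#'
#' @param df data.frame with columns `species`, `chromosome` and
#'   `length_bp`; (species, chromosome) pairs must be unique and lengths
#'   positive.
#' @return validated data.frame of class `ChromosomeInfo`.
#' @export
chromosome_info <- function(df) {
  need <- c("species", "chromosome", "length_bp")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("chromosome table lacks column(s): %s",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$species <- as.character(df$species)
  df$chromosome <- as.character(df$chromosome)
  df$length_bp <- as.numeric(df$length_bp)
  if (anyNA(df$length_bp) || any(df$length_bp <= 0)) {
    abort_validation("chromosome lengths must be positive")
  }
  key <- paste(df$species, df$chromosome, sep = ":")
  if (anyDuplicated(key)) {
    abort_validation("duplicate (species, chromosome) entries")
  }
  class(df) <- c("ChromosomeInfo", "data.frame")
  df
}

#' Read chromosome lengths from TSV
#'
#' Accepts either a three-column table (`species`, `chromosome`,
#' `length_bp`) or the two-column form (`chromosome`, `length_bp`) with
#' the species supplied as an argument.
#'
#' @param path path to the TSV.
#' @param species species label for two-column tables.
#' @return a `ChromosomeInfo` data.frame.
#' @export
read_chrom_lengths <- function(path, species = NULL) {
  df <- read_tsv(path)
  if (!"species" %in% names(df)) {
    if (is.null(species)) {
      abort_argument("two-column length tables need a `species` argument")
    }
    df$species <- species
  }
  if ("name" %in% names(df) && !"chromosome" %in% names(df)) {
    names(df)[names(df) == "name"] <- "chromosome"
  }
  chromosome_info(df[, c("species", "chromosome", "length_bp")])
}

#' Construct a table of gene loci
#'
#' Coordinates are 1-based and inclusive at this interface (the GFF3
#' convention). Every locus must lie within its chromosome as given in
#' `chrom_info`.
#'
#' @param df data.frame with columns `species`, `gene_id`, `chromosome`,
#'   `start_bp`, `end_bp` and optionally `strand` (`+`, `-` or `*`).
#' @param chrom_info a `ChromosomeInfo` table for bounds checking.
#' @return validated data.frame of class `GeneLocusTable`.
#' @export
gene_loci <- function(df, chrom_info) {
  need <- c("species", "gene_id", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("locus table lacks column(s): %s",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!"strand" %in% names(df)) df$strand <- "*"
  df$species <- as.character(df$species)
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$start_bp <- as.numeric(df$start_bp)
  df$end_bp <- as.numeric(df$end_bp)
  if (any(df$start_bp < 1) || any(df$start_bp > df$end_bp)) {
    abort_validation("need 1 <= start_bp <= end_bp for every locus")
  }
  key <- paste(df$species, df$chromosome, sep = ":")
  ckey <- paste(chrom_info$species, chrom_info$chromosome, sep = ":")
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    abort_validation(sprintf("loci on unknown chromosome(s): %s",
                             paste(unique(key[is.na(idx)]), collapse = ", ")))
  }
  too_far <- df$end_bp > chrom_info$length_bp[idx]
  if (any(too_far)) {
    abort_validation(sprintf("locus extends beyond chromosome end: %s",
                             paste(df$gene_id[too_far], collapse = ", ")))
  }
  class(df) <- c("GeneLocusTable", "data.frame")
  df
}

#' Read gene loci from GFF3 or BED
#'
#' GFF3 coordinates are used as-is (1-based inclusive); BED intervals are
#' 0-based half-open and are converted on import. For GFF3, features of
#' type `gene` are used when present; the gene identifier is taken from
#' the `gene_id`, `ID` or `Name` attribute (first available). BED uses
#' the name column.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param species species label attached to every locus.
#' @param chrom_info a `ChromosomeInfo` table for bounds checking.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return a `GeneLocusTable`.
#' @export
read_gene_loci <- function(path, species, chrom_info, format = "auto") {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
      else if (ext == "bed") "bed"
      else abort_argument(sprintf("cannot infer format from extension '%s'", ext))
  }
  gr <- if (format == "gff3") {
    rtracklayer::import(path, format = "gff3")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  md <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(md) && any(md$type == "gene")) {
    md <- md[md$type == "gene", , drop = FALSE]
  }
  id_col <- intersect(c("gene_id", "ID", "Name", "name"), names(md))
  if (!length(id_col)) abort_parse("no gene identifier attribute found")
  ids <- as.character(md[[id_col[1]]])
  if (anyNA(ids) || any(!nzchar(ids))) abort_parse("missing gene identifiers")
  gene_loci(data.frame(
    species = species, gene_id = ids,
    chromosome = as.character(md$seqnames),
    start_bp = md$start, end_bp = md$end,
    strand = as.character(md$strand),
    stringsAsFactors = FALSE), chrom_info)
}

#' Distance from a gene to the nearest telomere
#'
#' Computes `min(start_bp - 1, length_bp - end_bp) / 1e6`: the distance,
#' in megabases, from the gene to the nearest chromosome end. Per-arm
#' distances are available via `arm`.
#'
#' @param start_bp,end_bp 1-based inclusive gene coordinates (vectorized).
#' @param chrom_length_bp chromosome length in bp.
#' @param arm `"nearest"` (default), `"p"` (distance to the start of the
#'   chromosome) or `"q"` (distance to the end).
#' @return distance in Mb (numeric vector).
#' @export
telomere_distance <- function(start_bp, end_bp, chrom_length_bp,
                              arm = c("nearest", "p", "q")) {
  arm <- match.arg(arm)
  if (any(start_bp < 1) || any(start_bp > end_bp) ||
      any(end_bp > chrom_length_bp)) {
    abort_validation("locus must satisfy 1 <= start_bp <= end_bp <= chromosome length")
  }
  d_p <- start_bp - 1
  d_q <- chrom_length_bp - end_bp
  switch(arm,
         nearest = pmin(d_p, d_q),
         p = d_p,
         q = d_q) / 1e6
}

#' Telomere-proximity factor F(i)
#'
#' A gene is proximal to a telomere when its nearest-end distance is
#' strictly below the threshold (default 50 Mb); a gene exactly at the
#' threshold is non-proximal.
#'
#' @param distance_mb non-negative distance(s) in Mb.
#' @param threshold_mb proximity threshold in Mb (default 50).
#' @return logical vector.
#' @export
classify_f_i <- function(distance_mb, threshold_mb = 50) {
  if (any(distance_mb < 0)) abort_argument("distances must be non-negative")
  if (!is_scalar_number(threshold_mb) || threshold_mb <= 0) {
    abort_argument("`threshold_mb` must be positive")
  }
  distance_mb < threshold_mb
}

#' A+T fraction of a nucleotide sequence
#'
#' Counts adenine and thymine over the unambiguous bases (A, C, G, T);
#' ambiguity codes such as N are excluded from the denominator.
#'
#' @param sequence a non-empty nucleotide string (case-insensitive,
#'   IUPAC letters) or a `Biostrings::DNAString`.
#' @return A+T fraction in \[0, 1\].
#' @export
at_content <- function(sequence) {
  if (!inherits(sequence, "DNAString")) {
    if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
      abort_argument("`sequence` must be a single non-empty string")
    }
    sequence <- tryCatch(Biostrings::DNAString(toupper(sequence)),
                         error = function(e) abort_parse(
                           sprintf("invalid nucleotide sequence: %s",
                                   conditionMessage(e))))
  }
  counts <- Biostrings::letterFrequency(sequence, c("A", "C", "G", "T"))
  if (is.matrix(counts)) counts <- counts[1, ]
  denom <- sum(counts)
  if (denom == 0) abort_argument("sequence has no unambiguous bases")
  unname((counts[["A"]] + counts[["T"]]) / denom)
}

#' High A+T content factor F(ii)
#'
#' TRUE when the A+T fraction strictly exceeds the threshold, whose
#' default 0.59 is the average A+T content of human chromosomes; the
#' boundary value is not called high.
#'
#' @param at_fraction A+T fraction(s) in \[0, 1\].
#' @param threshold fraction threshold (default 0.59).
#' @return logical vector.
#' @export
classify_f_ii <- function(at_fraction, threshold = 0.59) {
  if (any(at_fraction < 0 | at_fraction > 1)) {
    abort_argument("A+T fractions must lie in [0, 1]")
  }
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    abort_argument("`threshold` must lie in [0, 1]")
  }
  at_fraction > threshold
}

#' Per-gene mutability factor calls
#'
#' For every locus, computes the nearest-telomere distance and the F(i)
#' proximity call; when genomic sequence is supplied, also the A+T
#' fraction over the gene span and the F(ii) call. Sequences are given as
#' a named list `species -> DNAStringSet` keyed by chromosome name. When
#' both sequence and a length table are present, their chromosome lengths
#' must agree.
#'
#' @param loci a `GeneLocusTable`.
#' @param chrom_info a `ChromosomeInfo` table.
#' @param sequences optional named list of `DNAStringSet` per species.
#' @param threshold_mb F(i) threshold in Mb (default 50).
#' @param threshold_at F(ii) threshold fraction (default 0.59).
#' @param arm telomere-distance mode, see [telomere_distance()].
#' @return data.frame of class `FactorCallTable` with `gene_id`,
#'   `species`, `telomere_distance_mb`, `f_i`, `at_fraction`, `f_ii`.
#' @export
factor_calls <- function(loci, chrom_info, sequences = NULL,
                         threshold_mb = 50, threshold_at = 0.59,
                         arm = "nearest") {
  loci <- gene_loci(as.data.frame(loci), chrom_info)
  ckey <- paste(chrom_info$species, chrom_info$chromosome, sep = ":")
  idx <- match(paste(loci$species, loci$chromosome, sep = ":"), ckey)
  len <- chrom_info$length_bp[idx]
  dist_mb <- telomere_distance(loci$start_bp, loci$end_bp, len, arm = arm)
  at_frac <- rep(NA_real_, nrow(loci))
  if (!is.null(sequences)) {
    for (i in seq_len(nrow(loci))) {
      sp <- loci$species[i]
      chr <- loci$chromosome[i]
      if (!sp %in% names(sequences) || !chr %in% names(sequences[[sp]])) next
      seq_chr <- sequences[[sp]][[chr]]
      if (length(seq_chr) != len[i]) {
        abort_validation(sprintf(
          "length table (%d bp) and FASTA (%d bp) disagree for %s:%s",
          len[i], length(seq_chr), sp, chr))
      }
      span <- Biostrings::subseq(seq_chr, loci$start_bp[i], loci$end_bp[i])
      at_frac[i] <- at_content(span)
    }
  }
  out <- data.frame(
    gene_id = loci$gene_id, species = loci$species,
    telomere_distance_mb = dist_mb,
    f_i = classify_f_i(dist_mb, threshold_mb),
    at_fraction = at_frac,
    f_ii = ifelse(is.na(at_frac), NA, classify_f_ii(pmin(pmax(at_frac, 0), 1),
                                                    threshold_at)),
    stringsAsFactors = FALSE)
  class(out) <- c("FactorCallTable", "data.frame")
  out
}

#' Matching rate of a gene panel against a mutability factor
#'
#' Percentage of a species' panel genes whose factor flag is TRUE. The
#' exact fraction is retained; `rate_percent` is rounded to the nearest
#' integer percent for reporting.
#'
#' @param calls a `FactorCallTable` (see [factor_calls()]).
#' @param species species label to summarize.
#' @param factor `"f_i"` or `"f_ii"`.
#' @return list of class `MatchingRateSummary` with `species`, `factor`,
#'   `n_genes`, `n_matching`, `rate_percent` (integer) and `rate_exact`.
#' @export
matching_rate <- function(calls, species, factor = c("f_i", "f_ii")) {
  factor <- match.arg(factor)
  sub <- calls[calls$species == species, , drop = FALSE]
  if (!nrow(sub)) {
    abort_argument(sprintf("no factor calls for species '%s'", species))
  }
  flags <- sub[[factor]]
  if (anyNA(flags)) {
    abort_argument(sprintf("missing %s calls for species '%s'", factor, species))
  }
  n <- length(flags)
  k <- sum(flags)
  structure(list(species = species, factor = factor, n_genes = n,
                 n_matching = k, rate_percent = round(100 * k / n),
                 rate_exact = 100 * k / n),
            class = "MatchingRateSummary")
}

#' Genetic linkage call from recombination frequency
#'
#' Two loci are linked when their recombination frequency is 50
#' centimorgans or less (inclusive) and unlinked above 50 cM.
#'
#' @param recombination_cM non-negative recombination frequency(ies).
#' @return character vector, `"linked"` or `"unlinked"`.
#' @export
linkage_status <- function(recombination_cM) {
  if (any(recombination_cM < 0)) {
    abort_argument("recombination frequency must be non-negative")
  }
  ifelse(recombination_cM <= 50, "linked", "unlinked")
}

#' Convert genetic distance to physical distance
#'
#' Uses the standard coarse equivalence 1 cM ~ 1 Mb.
#'
#' @param genetic_distance_cM non-negative distance(s) in centimorgans.
#' @return physical distance in Mb.
#' @export
cm_to_mb <- function(genetic_distance_cM) {
  if (any(genetic_distance_cM < 0)) {
    abort_argument("genetic distance must be non-negative")
  }
  genetic_distance_cM * 1
}

#' Reference transcript-size range
#'
#' @param min_bp,max_bp positive bounds with `min_bp <= max_bp`.
#' @param panel_name label for the reference panel.
#' @return list of class `ReferenceSizeRange`.
#' @export
reference_size_range <- function(min_bp, max_bp, panel_name = "reference") {
  if (!is_scalar_number(min_bp) || !is_scalar_number(max_bp) ||
      min_bp <= 0 || max_bp < min_bp) {
    abort_argument("need 0 < min_bp <= max_bp")
  }
  structure(list(panel_name = panel_name, min_bp = min_bp, max_bp = max_bp),
            class = "ReferenceSizeRange")
}

#' Read per-species transcript lengths from TSV
#'
#' Columns: `species`, `gene_id`, `transcript_length_bp`.
#'
#' @param path path to the TSV.
#' @return data.frame of transcript records.
#' @export
read_transcript_lengths <- function(path) {
  df <- read_tsv(path)
  need <- c("species", "gene_id", "transcript_length_bp")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("transcript table lacks column(s): %s",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$transcript_length_bp <- as.numeric(df$transcript_length_bp)
  if (anyNA(df$transcript_length_bp) || any(df$transcript_length_bp <= 0)) {
    abort_validation("transcript lengths must be positive")
  }
  df
}

#' Cross-species transcript-size conservation
#'
#' Flags each species' transcript as `"typical"` when its length lies
#' inside the reference panel range and `"unusual"` otherwise, and
#' reports the max/min length ratio across species as a conservation
#' score (1 = perfectly conserved).
#'
#' @param records data.frame with columns `species` and
#'   `transcript_length_bp` for one gene across >= 2 species.
#' @param reference a [reference_size_range()].
#' @return list of class `SizeConservation` with `flags` (data.frame:
#'   `species`, `transcript_length_bp`, `flag`) and `length_ratio`.
#' @export
size_conservation <- function(records, reference) {
  if (!inherits(reference, "ReferenceSizeRange")) {
    abort_argument("`reference` must be a reference_size_range()")
  }
  need <- c("species", "transcript_length_bp")
  if (!all(need %in% names(records))) {
    abort_argument("`records` must carry species and transcript_length_bp")
  }
  if (nrow(records) < 2L) {
    abort_argument("size conservation needs >= 2 species")
  }
  len <- records$transcript_length_bp
  if (any(len <= 0)) abort_validation("transcript lengths must be positive")
  flag <- ifelse(len >= reference$min_bp & len <= reference$max_bp,
                 "typical", "unusual")
  structure(list(
    flags = data.frame(species = records$species,
                       transcript_length_bp = len, flag = flag,
                       stringsAsFactors = FALSE),
    length_ratio = max(len) / min(len),
    panel_name = reference$panel_name),
    class = "SizeConservation")
}
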