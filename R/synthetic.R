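# Synthetic-data generators: every generator is a pure function of its
# spec plus seed, and emits truth records sufficient to score downstream
# stages without inspecting generator internals.

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Specification for a simulated FPKM cohort
#'
#' Defaults emulate the small postmortem cohort the analysis targets:
#' n = 5 control, 6 AD and 3 PD samples acquired in two sessions (the
#' first three samples of each group belong to session 1, mirroring a
#' preliminary batch of n = 3 per group), heavy-tailed non-negative FPKM
#' values from a log-normal baseline, spiked per-gene group effects, and
#' one control sample (`outlier_control_index = 3`) whose spiked genes
#' follow the AD distribution so that it clusters with the disease
#' samples.
#'
#' @param n_genes number of genes.
#' @param group_sizes named counts for `control`, `AD`, `PD` (all >= 1).
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of
#'   the per-gene baseline (defaults give a median around 15 FPKM with an
#'   upper tail reaching several hundred, bracketing typical printed
#'   values).
#' @param spike_table optional data.frame with columns `gene_index`,
#'   `group`, `fold` (>= 1) and `direction` (`"up"`/`"down"`).
#' @param batch_effect_sd sd of the gene-specific session-2 log shift.
#' @param noise_log_sd sd of per-cell log-normal noise.
#' @param outlier_control_index index (within the control group) of the
#'   disease-like control sample, or `NULL` for none.
#' @param seed integer seed.
#' @return list of class `ExpressionSimSpec`.
#' @export
expression_sim_spec <- function(n_genes = 2000L,
                                group_sizes = c(control = 5L, AD = 6L, PD = 3L),
                                baseline_log_mean = log(15),
                                baseline_log_sd = 1.6,
                                spike_table = NULL,
                                batch_effect_sd = 0.2,
                                noise_log_sd = 0.4,
                                outlier_control_index = 3L,
                                seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) abort_argument("`n_genes` must be >= 1")
  if (is.null(names(group_sizes)) ||
      !all(c("control") %in% names(group_sizes)) ||
      any(group_sizes < 1)) {
    abort_argument("`group_sizes` must be named counts >= 1 including 'control'")
  }
  if (!is.null(spike_table)) {
    need <- c("gene_index", "group", "fold", "direction")
    if (!all(need %in% names(spike_table))) {
      abort_argument("spike_table needs gene_index, group, fold, direction")
    }
    if (any(spike_table$gene_index < 1) || any(spike_table$gene_index > n_genes)) {
      abort_argument("spike gene_index out of range")
    }
    if (any(spike_table$fold < 1)) abort_argument("spike folds must be >= 1")
    if (!all(spike_table$direction %in% c("up", "down"))) {
      abort_argument("spike direction must be 'up' or 'down'")
    }
    if (!all(spike_table$group %in% setdiff(names(group_sizes), "control"))) {
      abort_argument("spike group must be a non-control group")
    }
  }
  if (!is.null(outlier_control_index) &&
      (!is_count(outlier_control_index) ||
       outlier_control_index < 1 ||
       outlier_control_index > group_sizes[["control"]])) {
    abort_argument("`outlier_control_index` must index a control sample")
  }
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = group_sizes,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 spike_table = spike_table,
                 batch_effect_sd = batch_effect_sd,
                 noise_log_sd = noise_log_sd,
                 outlier_control_index = outlier_control_index,
                 seed = as.integer(seed)),
            class = "ExpressionSimSpec")
}

#' Simulate an FPKM cohort with known group effects
#'
#' Per-gene baseline log-means are drawn once; each cell is
#' `exp(log mean + spike + batch shift + noise)`, hence strictly
#' positive with a heavy right tail. Spiked genes have the log mean of
#' their target group shifted by `+/- log(fold)`; the optional outlier
#' control sample additionally inherits the AD-group spikes, emulating a
#' control specimen that is transcriptomically disease-like.
#'
#' @param spec an [expression_sim_spec()].
#' @return list of class `FpkmSimulation` with `matrix`
#'   ([ExpressionMatrix]), `metadata` (`SampleMetadata`) and `truth`
#'   (data.frame `entity`, `property`, `value`).
#' @export
simulate_fpkm <- function(spec) {
  if (!inherits(spec, "ExpressionSimSpec")) {
    abort_argument("`spec` must be an expression_sim_spec()")
  }
  gs <- spec$group_sizes
  groups <- rep(names(gs), times = gs)
  within_idx <- unlist(lapply(gs, seq_len), use.names = FALSE)
  samples <- paste0(groups, "_", within_idx)
  batch <- ifelse(within_idx <= 3L, "session1", "session2")
  n_s <- length(samples)
  ng <- spec$n_genes

  out <- with_seed(spec$seed, {
    mu <- stats::rnorm(ng, spec$baseline_log_mean, spec$baseline_log_sd)
    delta <- matrix(0, ng, n_s)
    outlier_col <- if (!is.null(spec$outlier_control_index)) {
      which(groups == "control" & within_idx == spec$outlier_control_index)
    } else {
      integer(0)
    }
    st <- spec$spike_table
    if (!is.null(st)) {
      for (r in seq_len(nrow(st))) {
        shift <- (if (st$direction[r] == "up") 1 else -1) * log(st$fold[r])
        cols <- which(groups == st$group[r])
        delta[st$gene_index[r], cols] <- delta[st$gene_index[r], cols] + shift
        if (length(outlier_col) && st$group[r] == "AD") {
          delta[st$gene_index[r], outlier_col] <- shift
        }
      }
    }
    bshift <- stats::rnorm(ng, 0, spec$batch_effect_sd)
    logv <- mu + delta
    logv[, batch == "session2"] <- logv[, batch == "session2"] + bshift
    noise <- matrix(stats::rnorm(ng * n_s, 0, spec$noise_log_sd), ng, n_s)
    exp(logv + noise)
  })

  m <- ExpressionMatrix(out, gene_ids = sim_gene_ids(ng), sample_ids = samples)
  meta <- SampleMetadata(data.frame(sample_id = samples, group = groups,
                                    batch = batch, stringsAsFactors = FALSE),
                         groups = names(gs))
  truth <- data.frame(entity = character(), property = character(),
                      value = character(), stringsAsFactors = FALSE)
  st <- spec$spike_table
  if (!is.null(st)) {
    gid <- sim_gene_ids(ng)[st$gene_index]
    truth <- rbind(truth,
      data.frame(entity = gid,
                 property = paste0("true_fold_", st$group),
                 value = as.character(st$fold), stringsAsFactors = FALSE),
      data.frame(entity = gid,
                 property = paste0("true_direction_", st$group),
                 value = st$direction, stringsAsFactors = FALSE))
  }
  if (!is.null(spec$outlier_control_index)) {
    truth <- rbind(truth, data.frame(
      entity = paste0("control_", spec$outlier_control_index),
      property = "outlier_control", value = "TRUE", stringsAsFactors = FALSE))
  }
  structure(list(matrix = m, metadata = meta, truth = truth, spec = spec),
            class = "FpkmSimulation")
}

#' Specification for a synthetic genome
#'
#' @param chromosomes data.frame with columns `name` and `length_bp`.
#' @param placements data.frame with columns `gene_id`, `chromosome`,
#'   `target_telomere_distance_mb`, `length_bp`,
#'   `target_at_fraction` (in (0, 1\]).
#' @param species species label (default `"synthetic"`).
#' @param background_at A+T fraction of intergenic background (default
#'   0.5).
#' @param seed integer seed.
#' @return list of class `GenomeSimSpec`.
#' @export
genome_sim_spec <- function(chromosomes, placements, species = "synthetic",
                            background_at = 0.5, seed = 1L) {
  if (!all(c("name", "length_bp") %in% names(chromosomes))) {
    abort_argument("`chromosomes` needs columns name and length_bp")
  }
  need <- c("gene_id", "chromosome", "target_telomere_distance_mb",
            "length_bp", "target_at_fraction")
  if (!all(need %in% names(placements))) {
    abort_argument(sprintf("`placements` needs columns: %s",
                           paste(need, collapse = ", ")))
  }
  if (any(placements$target_at_fraction <= 0 |
          placements$target_at_fraction > 1)) {
    abort_argument("target A+T fractions must lie in (0, 1]")
  }
  if (!all(placements$chromosome %in% chromosomes$name)) {
    abort_argument("placement on unknown chromosome")
  }
  structure(list(chromosomes = chromosomes, placements = placements,
                 species = species, background_at = background_at,
                 seed = as.integer(seed)),
            class = "GenomeSimSpec")
}

# Draw `len` bases with an exact A+T base count of round(at * len).
draw_bases <- function(len, at) {
  n_at <- round(at * len)
  is_at <- logical(len)
  is_at[sample.int(len, n_at)] <- TRUE
  bases <- character(len)
  bases[is_at] <- sample(c("A", "T"), n_at, replace = TRUE)
  bases[!is_at] <- sample(c("C", "G"), len - n_at, replace = TRUE)
  bases
}

#' Simulate a genome with controlled telomere distances and A+T content
#'
#' Builds chromosome sequences whose gene spans carry an exact A+T base
#' count (`round(target * length)`, so the realized fraction is within
#' half a base of the target) and places each gene so that its
#' nearest-end telomere distance equals the target exactly. Placement is
#' tried on the left arm first, then the right; an impossible placement
#' (target distance or gene length too large for the chromosome) is an
#' error.
#'
#' @param spec a [genome_sim_spec()].
#' @return list of class `GenomeSimulation` with `sequences` (named list
#'   `species -> DNAStringSet`), `loci` (`GeneLocusTable`), `chrom_info`
#'   (`ChromosomeInfo`) and `truth` (data.frame).
#' @export
simulate_genome <- function(spec) {
  if (!inherits(spec, "GenomeSimSpec")) {
    abort_argument("`spec` must be a genome_sim_spec()")
  }
  chrom_info <- chromosome_info(data.frame(
    species = spec$species, chromosome = spec$chromosomes$name,
    length_bp = spec$chromosomes$length_bp, stringsAsFactors = FALSE))
  pl <- spec$placements
  res <- with_seed(spec$seed, {
    seqs <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
      draw_bases(spec$chromosomes$length_bp[i], spec$background_at)
    })
    names(seqs) <- spec$chromosomes$name
    starts <- numeric(nrow(pl))
    ends <- numeric(nrow(pl))
    for (i in seq_len(nrow(pl))) {
      L <- spec$chromosomes$length_bp[spec$chromosomes$name == pl$chromosome[i]]
      len <- pl$length_bp[i]
      d <- round(pl$target_telomere_distance_mb[i] * 1e6)
      s_left <- d + 1
      e_left <- s_left + len - 1
      if (e_left <= L && (L - e_left) >= d) {
        starts[i] <- s_left
        ends[i] <- e_left
      } else {
        e_right <- L - d
        s_right <- e_right - len + 1
        if (s_right >= 1 && (s_right - 1) >= d) {
          starts[i] <- s_right
          ends[i] <- e_right
        } else {
          abort_argument(sprintf(
            "infeasible placement for %s: distance %g Mb + length %d bp on a %d bp chromosome",
            pl$gene_id[i], pl$target_telomere_distance_mb[i], len, L))
        }
      }
      seqs[[pl$chromosome[i]]][starts[i]:ends[i]] <-
        draw_bases(len, pl$target_at_fraction[i])
    }
    list(seqs = seqs, starts = starts, ends = ends)
  })
  dna <- Biostrings::DNAStringSet(vapply(res$seqs, paste, character(1),
                                         collapse = ""))
  loci <- gene_loci(data.frame(
    species = spec$species, gene_id = pl$gene_id,
    chromosome = pl$chromosome, start_bp = res$starts, end_bp = res$ends,
    strand = "+", stringsAsFactors = FALSE), chrom_info)
  truth <- rbind(
    data.frame(entity = pl$gene_id, property = "true_telomere_distance_mb",
               value = as.character(pl$target_telomere_distance_mb),
               stringsAsFactors = FALSE),
    data.frame(entity = pl$gene_id, property = "true_at_fraction",
               value = as.character(round(pl$target_at_fraction * pl$length_bp) /
                                      pl$length_bp),
               stringsAsFactors = FALSE))
  sequences <- list(dna)
  names(sequences) <- spec$species
  structure(list(sequences = sequences, loci = loci,
                 chrom_info = chrom_info, truth = truth, spec = spec),
            class = "GenomeSimulation")
}

#' Write a simulated genome to FASTA, GFF3 and a length table
#'
#' @param sim a `GenomeSimulation`.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_genome <- function(sim, dir) {
  if (!inherits(sim, "GenomeSimulation")) {
    abort_argument("`sim` must be a GenomeSimulation")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(sim$sequences[[1]], fasta)
  gff <- file.path(dir, "genes.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = sim$loci$chromosome,
    ranges = IRanges::IRanges(sim$loci$start_bp, sim$loci$end_bp),
    strand = sim$loci$strand)
  gr$type <- "gene"
  gr$ID <- sim$loci$gene_id
  gr$gene_id <- sim$loci$gene_id
  rtracklayer::export(gr, gff, format = "gff3")
  lengths <- file.path(dir, "chrom_lengths.tsv")
  write_tsv(data.frame(species = sim$chrom_info$species,
                       chromosome = sim$chrom_info$chromosome,
                       length_bp = sim$chrom_info$length_bp), lengths)
  list(fasta = fasta, gff3 = gff, chrom_lengths = lengths)
}

#' Simulate a gene-set collection with one designed enriched set
#'
#' Draws `n_sets` member lists uniformly from the simulated gene universe
#' and augments the expression spec so the first set's members are spiked
#' up by `enriched_set_fold` in both disease groups (no spike when the
#' fold is 1, the null case). The truth record names the enriched set.
#'
#' @param n_sets number of sets (>= 2).
#' @param set_size members per set (<= `matrix_spec$n_genes`).
#' @param enriched_set_fold fold applied to the designated set (>= 1).
#' @param matrix_spec an [expression_sim_spec()] describing the cohort.
#' @param seed integer seed for membership draws.
#' @return list of class `GeneSetSimulation` with `sets` (list of
#'   [gene_set()]), `spec` (the augmented expression spec) and `truth`.
#' @export
simulate_gene_sets <- function(n_sets, set_size, enriched_set_fold,
                               matrix_spec, seed = 1L) {
  if (!is_count(n_sets) || n_sets < 2L) abort_argument("`n_sets` must be >= 2")
  if (!inherits(matrix_spec, "ExpressionSimSpec")) {
    abort_argument("`matrix_spec` must be an expression_sim_spec()")
  }
  if (!is_count(set_size) || set_size < 1L ||
      set_size > matrix_spec$n_genes) {
    abort_argument("`set_size` must lie in [1, n_genes]")
  }
  if (!is_scalar_number(enriched_set_fold) || enriched_set_fold < 1) {
    abort_argument("`enriched_set_fold` must be >= 1")
  }
  ids <- sim_gene_ids(matrix_spec$n_genes)
  members <- with_seed(seed, lapply(seq_len(n_sets), function(i) {
    sort(sample.int(matrix_spec$n_genes, set_size))
  }))
  set_names <- sprintf("SET_%02d", seq_len(n_sets))
  sets <- lapply(seq_len(n_sets), function(i) {
    gene_set(set_names[i], ids[members[[i]]],
             description = if (i == 1L && enriched_set_fold > 1)
               "designed enriched set" else "random set")
  })
  names(sets) <- set_names
  spec <- matrix_spec
  if (enriched_set_fold > 1) {
    disease <- setdiff(names(spec$group_sizes), "control")
    spikes <- expand.grid(gene_index = members[[1L]], group = disease,
                          stringsAsFactors = FALSE)
    spikes$fold <- enriched_set_fold
    spikes$direction <- "up"
    spec <- expression_sim_spec(
      n_genes = spec$n_genes, group_sizes = spec$group_sizes,
      baseline_log_mean = spec$baseline_log_mean,
      baseline_log_sd = spec$baseline_log_sd,
      spike_table = rbind(spec$spike_table, spikes),
      batch_effect_sd = spec$batch_effect_sd,
      noise_log_sd = spec$noise_log_sd,
      outlier_control_index = spec$outlier_control_index,
      seed = spec$seed)
  }
  truth <- data.frame(
    entity = set_names[1L], property = "enriched_set",
    value = as.character(enriched_set_fold), stringsAsFactors = FALSE)
  structure(list(sets = sets, spec = spec, truth = truth),
            class = "GeneSetSimulation")
}

#' Write truth records as a JSON sidecar
#'
#' @param truth data.frame with `entity`, `property`, `value`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
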