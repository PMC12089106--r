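# Pipeline orchestration: a declarative JSON config drives
# simulate -> ingest/filter -> diffexpr -> structure -> enrichment ->
# mutability -> report. Stages communicate only through serialized
# outputs in the run directory; a manifest records config, checksums and
# timings so identical configs reproduce identical outputs.

PIPELINE_STAGES <- c("simulate", "ingest", "de", "pca", "cluster",
                     "enrich", "mutability", "report")

cfg_get <- function(cfg, ..., default = NULL) {
  keys <- c(...)
  node <- cfg
  for (k in keys) {
    if (is.null(node[[k]])) return(default)
    node <- node[[k]]
  }
  node
}

#' Load and validate a pipeline configuration
#'
#' The config is a JSON document (or an equivalent R list) with a
#' required `output_dir` and `seed`, plus per-stage blocks (`simulate`,
#' `input`, `filter`, `diffexpr`, `pca`, `cluster`, `enrichment`,
#' `mutability`). Referenced input files must exist at load time; every
#' random stage derives its stream from the single top-level seed.
#'
#' @param config path to a JSON file, or a list.
#' @return validated config list.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      cn_abort(sprintf("config file not found: %s", config), "cnseq_config_error")
    }
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) {
    config
  } else {
    cn_abort("`config` must be a path or a list", "cnseq_config_error")
  }
  if (is.null(cfg$output_dir)) {
    cn_abort("config requires `output_dir`", "cnseq_config_error")
  }
  if (is.null(cfg$seed)) {
    cn_abort("config requires an explicit `seed` (no wall-clock seeding)",
             "cnseq_config_error")
  }
  paths <- c(cfg_get(cfg, "input", "fpkm"), cfg_get(cfg, "input", "metadata"),
             cfg_get(cfg, "enrichment", "gmt"),
             cfg_get(cfg, "mutability", "loci"),
             cfg_get(cfg, "mutability", "chrom_lengths"),
             cfg_get(cfg, "mutability", "fasta"),
             cfg_get(cfg, "mutability", "transcripts"))
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    cn_abort(sprintf("config references missing file(s): %s",
                     paste(missing, collapse = ", ")), "cnseq_config_error")
  }
  thr_mb <- cfg_get(cfg, "mutability", "threshold_mb", default = 50)
  thr_at <- cfg_get(cfg, "mutability", "threshold_at", default = 0.59)
  if (thr_mb <= 0 || thr_at <= 0) {
    cn_abort("mutability thresholds must be positive", "cnseq_config_error")
  }
  cfg
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_simulate <- function(cfg, state, out_dir) {
  sim_cfg <- cfg$simulate %||% list()
  spec <- expression_sim_spec(
    n_genes = cfg_get(sim_cfg, "n_genes", default = 2000L),
    group_sizes = unlist(cfg_get(sim_cfg, "group_sizes",
                                 default = c(control = 5L, AD = 6L, PD = 3L))),
    baseline_log_mean = cfg_get(sim_cfg, "baseline_log_mean", default = log(15)),
    baseline_log_sd = cfg_get(sim_cfg, "baseline_log_sd", default = 1.6),
    spike_table = if (!is.null(sim_cfg$spike_table))
      as.data.frame(sim_cfg$spike_table) else NULL,
    batch_effect_sd = cfg_get(sim_cfg, "batch_effect_sd", default = 0.2),
    noise_log_sd = cfg_get(sim_cfg, "noise_log_sd", default = 0.4),
    outlier_control_index = {
      # 0 disables the disease-like control (JSON has no NULL)
      oi <- cfg_get(sim_cfg, "outlier_control_index", default = 3L)
      if (identical(as.numeric(oi), 0)) NULL else oi
    },
    seed = derive_seed(cfg$seed, 1L))
  outputs <- character()
  gs_cfg <- sim_cfg$gene_sets
  if (!is.null(gs_cfg)) {
    gs <- simulate_gene_sets(
      n_sets = cfg_get(gs_cfg, "n_sets", default = 8L),
      set_size = cfg_get(gs_cfg, "set_size", default = 50L),
      enriched_set_fold = cfg_get(gs_cfg, "enriched_set_fold", default = 4),
      matrix_spec = spec, seed = derive_seed(cfg$seed, 2L))
    spec <- gs$spec
    state$sets <- gs$sets
    gmt_path <- file.path(out_dir, "sets.gmt")
    write_gmt(gs$sets, gmt_path)
    outputs <- c(outputs, gmt_path)
  }
  sim <- simulate_fpkm(spec)
  fpkm_path <- file.path(out_dir, "fpkm.tsv")
  meta_path <- file.path(out_dir, "metadata.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  write_fpkm_table(sim$matrix, fpkm_path)
  write_tsv(as.data.frame(sim$metadata), meta_path)
  write_truth_json(sim$truth, truth_path)
  log_stage("simulate", "%d genes x %d samples", nrow(sim$matrix),
            ncol(sim$matrix))
  if (!is.null(sim_cfg$genome)) {
    gspec <- genome_sim_spec(
      chromosomes = as.data.frame(sim_cfg$genome$chromosomes),
      placements = as.data.frame(sim_cfg$genome$placements),
      species = cfg_get(sim_cfg, "genome", "species", default = "synthetic"),
      seed = derive_seed(cfg$seed, 3L))
    gsim <- simulate_genome(gspec)
    gpaths <- write_genome(gsim, file.path(out_dir, "genome"))
    state$genome <- gsim
    outputs <- c(outputs, unlist(gpaths))
  }
  state$fpkm_path <- fpkm_path
  state$meta_path <- meta_path
  c(outputs, fpkm_path, meta_path, truth_path)
}

stage_ingest <- function(cfg, state, out_dir) {
  fpkm_path <- cfg_get(cfg, "input", "fpkm") %||% state$fpkm_path
  meta_path <- cfg_get(cfg, "input", "metadata") %||% state$meta_path
  if (is.null(fpkm_path) || is.null(meta_path)) {
    abort_argument("no expression input: provide input.fpkm/metadata or enable simulate")
  }
  m <- read_fpkm_table(fpkm_path)
  meta <- read_sample_metadata(meta_path,
                               groups = cfg_get(cfg, "input", "groups",
                                                default = c("control", "AD", "PD")))
  validate_samples(m, meta)
  min_nz <- cfg_get(cfg, "filter", "min_samples_nonzero", default = 1L)
  mf <- filter_expressed(m, min_nz)
  log_stage("ingest", "%d of %d genes pass detection filter (min_samples_nonzero=%d)",
            nrow(mf), nrow(m), min_nz)
  state$m <- mf
  state$meta <- meta
  filt_path <- file.path(out_dir, "fpkm_filtered.tsv")
  write_fpkm_table(mf, filt_path)
  filt_path
}

stage_de <- function(cfg, state, out_dir) {
  contrasts <- cfg_get(cfg, "diffexpr", "contrasts",
                       default = c("AD-vs-control", "PD-vs-control"))
  test <- cfg_get(cfg, "diffexpr", "test", default = "welch")
  alpha <- cfg_get(cfg, "diffexpr", "alpha", default = 0.05)
  outputs <- character()
  state$de <- list()
  for (ct in contrasts) {
    tbl <- rank_genes(compare_groups(state$m, state$meta, ct, test = test))
    path <- file.path(out_dir, sprintf("de_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", ct)))
    write_de_table(tbl, path)
    summ <- significance_summary(tbl$p_value, alpha)
    log_stage("de", "%s: %d/%d significant at p < %g (%.1f%%)", ct,
              summ$n_significant, summ$n_total, alpha,
              round(summ$proportion_percent, 1))
    state$de[[ct]] <- list(table = tbl, summary = summ)
    outputs <- c(outputs, path)
  }
  outputs
}

stage_pca <- function(cfg, state, out_dir) {
  use_log <- cfg_get(cfg, "pca", "log", default = TRUE)
  standardize <- cfg_get(cfg, "pca", "standardize", default = TRUE)
  samples <- cfg_get(cfg, "pca", "samples")
  m <- state$m
  if (!is.null(samples)) {
    m <- ExpressionMatrix(unclass(m)[, samples, drop = FALSE])
  }
  input <- if (use_log) log_transform(m) else unclass(m)
  res <- pca_expression(input, standardize = standardize)
  state$pca <- res
  var_path <- file.path(out_dir, "pca_variance.tsv")
  write_tsv(data.frame(component = paste0("PC", seq_len(res$n_components)),
                       sdev = res$sdev,
                       variance_proportion = res$variance_proportion),
            var_path)
  load_path <- file.path(out_dir, "pca_loadings.tsv")
  write_tsv(data.frame(sample_id = rownames(res$loadings),
                       as.data.frame(res$loadings), check.names = FALSE),
            load_path)
  score_path <- file.path(out_dir, "pca_scores.tsv")
  write_tsv(data.frame(gene_id = rownames(res$scores),
                       as.data.frame(res$scores), check.names = FALSE),
            score_path)
  log_stage("pca", "PC1 accounts for %.1f%% of variance",
            100 * res$variance_proportion[1])
  c(var_path, load_path, score_path)
}

stage_cluster <- function(cfg, state, out_dir) {
  metric <- cfg_get(cfg, "cluster", "metric", default = "euclidean")
  linkage <- cfg_get(cfg, "cluster", "linkage", default = "ward")
  k <- cfg_get(cfg, "cluster", "gene_k", default = 8L)
  input <- log_transform(state$m)
  hc <- hierarchical_cluster(input, metric = metric, linkage = linkage)
  nwk_path <- file.path(out_dir, "dendrogram.nwk")
  dendrogram_newick(hc, nwk_path)
  k_eff <- min(k, nrow(input))
  gc <- gene_clusters(input, k = k_eff,
                      seed = derive_seed(cfg$seed, 4L),
                      linkage = cfg_get(cfg, "cluster", "gene_linkage",
                                        default = "average"))
  assign_path <- file.path(out_dir, "gene_clusters.tsv")
  write_tsv(gc$assignments, assign_path)
  prof_path <- file.path(out_dir, "cluster_profiles.tsv")
  write_tsv(data.frame(cluster = rownames(gc$profiles),
                       as.data.frame(gc$profiles), check.names = FALSE),
            prof_path)
  state$clusters <- gc
  log_stage("cluster", "samples clustered (%s/%s); %d gene subgroups",
            metric, linkage, k_eff)
  c(nwk_path, assign_path, prof_path)
}

stage_enrich <- function(cfg, state, out_dir) {
  gmt <- cfg_get(cfg, "enrichment", "gmt")
  sets <- if (!is.null(gmt)) read_gmt(gmt) else state$sets
  if (is.null(sets)) {
    abort_argument("no gene sets: provide enrichment.gmt or simulate.gene_sets")
  }
  contrast <- cfg_get(cfg, "enrichment", "contrast", default = "AD-vs-control")
  prof <- es_profile(state$m, state$meta, sets, contrast,
                     weight_p = cfg_get(cfg, "enrichment", "weight_p", default = 1),
                     n_perm = cfg_get(cfg, "enrichment", "n_perm", default = 1000L),
                     seed = derive_seed(cfg$seed, 5L))
  state$enrichment <- prof
  path <- file.path(out_dir, "enrichment.tsv")
  tbl <- prof$results
  tbl$n_perm <- cfg_get(cfg, "enrichment", "n_perm", default = 1000L)
  tbl$seed <- derive_seed(cfg$seed, 5L)
  write_tsv(tbl, path)
  log_stage("enrich", "%d sets scored on %s", nrow(prof$results), contrast)
  path
}

stage_mutability <- function(cfg, state, out_dir) {
  mcfg <- cfg$mutability %||% list()
  thr_mb <- cfg_get(mcfg, "threshold_mb", default = 50)
  thr_at <- cfg_get(mcfg, "threshold_at", default = 0.59)
  if (!is.null(mcfg$loci) && !is.null(mcfg$chrom_lengths)) {
    chrom_info <- read_chrom_lengths(mcfg$chrom_lengths,
                                     species = mcfg$species %||% NULL)
    species <- mcfg$species %||% unique(chrom_info$species)[1]
    loci <- read_gene_loci(mcfg$loci, species = species, chrom_info = chrom_info)
    sequences <- if (!is.null(mcfg$fasta)) {
      dna <- Biostrings::readDNAStringSet(mcfg$fasta)
      names(dna) <- sub("\\s.*$", "", names(dna))
      stats::setNames(list(dna), species)
    } else {
      NULL
    }
  } else if (!is.null(state$genome)) {
    gsim <- state$genome
    chrom_info <- gsim$chrom_info
    loci <- gsim$loci
    sequences <- gsim$sequences
  } else {
    abort_argument("no mutability inputs: provide mutability.loci/chrom_lengths or simulate.genome")
  }
  calls <- factor_calls(loci, chrom_info, sequences = sequences,
                        threshold_mb = thr_mb, threshold_at = thr_at)
  calls_path <- file.path(out_dir, "factor_calls.tsv")
  write_tsv(calls, calls_path)
  rates <- list()
  for (sp in unique(calls$species)) {
    for (f in c("f_i", "f_ii")) {
      if (anyNA(calls[[f]][calls$species == sp])) next
      mr <- matching_rate(calls, sp, f)
      rates[[paste(sp, f)]] <- data.frame(
        species = mr$species, factor = mr$factor, n_genes = mr$n_genes,
        n_matching = mr$n_matching, rate_percent = mr$rate_percent,
        rate_exact = mr$rate_exact, stringsAsFactors = FALSE)
    }
  }
  rates_df <- if (length(rates)) do.call(rbind, c(rates, make.row.names = FALSE))
    else data.frame()
  rates_path <- file.path(out_dir, "matching_rates.tsv")
  write_tsv(rates_df, rates_path)
  outputs <- c(calls_path, rates_path)
  if (!is.null(mcfg$transcripts)) {
    tr <- read_transcript_lengths(mcfg$transcripts)
    rng <- cfg_get(mcfg, "reference_range", default = c(1000, 8000))
    ref <- reference_size_range(rng[1], rng[2])
    cons <- lapply(split(tr, tr$gene_id), function(rec) {
      if (nrow(rec) < 2L) return(NULL)
      sc <- size_conservation(rec, ref)
      cbind(gene_id = rec$gene_id[1], sc$flags,
            length_ratio = sc$length_ratio)
    })
    cons_df <- do.call(rbind, c(Filter(Negate(is.null), cons),
                                make.row.names = FALSE))
    cons_path <- file.path(out_dir, "size_conservation.tsv")
    write_tsv(cons_df, cons_path)
    outputs <- c(outputs, cons_path)
  }
  state$mutability <- list(calls = calls, rates = rates_df)
  log_stage("mutability", "%d factor calls over %d species", nrow(calls),
            length(unique(calls$species)))
  outputs
}

stage_report <- function(cfg, state, out_dir) {
  rep <- report_from_dir(out_dir,
                         alpha = cfg_get(cfg, "diffexpr", "alpha", default = 0.05))
  json_path <- file.path(out_dir, "report.json")
  txt_path <- file.path(out_dir, "report.txt")
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(format_report(rep), txt_path)
  log_stage("report", "written to %s", json_path)
  c(json_path, txt_path)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in order (simulate, ingest, de, pca,
#' cluster, enrich, mutability, report). A stage failure stops the run
#' but leaves a manifest recording the completed stages, so the run can
#' be resumed after fixing the input.
#'
#' @param config config path or list, see [load_config()].
#' @param stages optional character subset of stages to run (prerequisite
#'   stages `simulate`/`ingest` are added automatically when expression
#'   data is needed).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config, stages = NULL) {
  cfg <- load_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  enabled <- if (!is.null(stages)) {
    bad <- setdiff(stages, PIPELINE_STAGES)
    if (length(bad)) {
      cn_abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
               "cnseq_config_error")
    }
    needs_expr <- intersect(stages, c("de", "pca", "cluster", "enrich"))
    extra <- if (length(needs_expr)) {
      c(if (is.null(cfg_get(cfg, "input", "fpkm"))) "simulate", "ingest")
    } else {
      NULL
    }
    intersect(PIPELINE_STAGES, union(stages, extra))
  } else {
    defaults_on <- c("ingest", "de", "pca", "cluster", "report")
    sel <- vapply(PIPELINE_STAGES, function(st) {
      block <- switch(st, simulate = cfg$simulate, ingest = cfg$filter,
                      de = cfg$diffexpr, pca = cfg$pca,
                      cluster = cfg$cluster, enrich = cfg$enrichment,
                      mutability = cfg$mutability, report = cfg$report)
      on <- block$enabled %||%
        (if (st == "mutability") {
           !is.null(block) || !is.null(cfg_get(cfg, "simulate", "genome"))
         } else if (st %in% c("simulate", "enrich")) {
           !is.null(block)
         } else {
           st %in% defaults_on
         })
      isTRUE(on) || identical(on, "true")
    }, logical(1))
    PIPELINE_STAGES[sel]
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnseq")),
    seed = cfg$seed, config = cfg, stages = list())
  state <- new.env(parent = emptyenv())
  manifest_path <- file.path(out_dir, "manifest.json")
  for (st in enabled) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(
      switch(st,
             simulate = stage_simulate(cfg, state, out_dir),
             ingest = stage_ingest(cfg, state, out_dir),
             de = stage_de(cfg, state, out_dir),
             pca = stage_pca(cfg, state, out_dir),
             cluster = stage_cluster(cfg, state, out_dir),
             enrich = stage_enrich(cfg, state, out_dir),
             mutability = stage_mutability(cfg, state, out_dir),
             report = stage_report(cfg, state, out_dir)),
      error = function(e) e)
    if (inherits(outputs, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(outputs))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           force = TRUE)
      cn_abort(sprintf("stage '%s' failed: %s", st, conditionMessage(outputs)),
               "cnseq_stage_error")
    }
    sums <- tools::md5sum(outputs)
    manifest$stages[[st]] <- list(
      status = "ok",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(stats::setNames(unname(sums), basename(outputs))))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}

#' Build a machine-readable summary from a run directory
#'
#' Reads whichever stage outputs exist under `out_dir` (never stage
#' internals) and assembles a single summary: top-ranked genes with star
#' labels, the significance proportion, the PC variance table, the
#' enrichment-score table and the mutability matching rates. Missing
#' stages simply yield empty sections, so an empty directory gives a
#' valid empty report.
#'
#' @param out_dir pipeline output directory.
#' @param alpha significance level for the proportion summary.
#' @param top_n number of top-ranked genes to include per contrast.
#' @return a named list (the report).
#' @export
report_from_dir <- function(out_dir, alpha = 0.05, top_n = 10L) {
  rep <- list(generated_by = paste0("cnseq ", utils::packageVersion("cnseq")),
              alpha = alpha)
  de_files <- list.files(out_dir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  de_section <- list()
  for (f in de_files) {
    tbl <- read_tsv(f)
    summ <- significance_summary(tbl$p_value, alpha)
    de_section[[tbl$contrast[1]]] <- list(
      n_total = summ$n_total,
      n_significant = summ$n_significant,
      proportion_percent = round(summ$proportion_percent, 1),
      top_genes = utils::head(
        tbl[order(tbl$rank), c("gene_id", "fold_change", "direction",
                               "p_value", "star_label", "rank")], top_n))
  }
  rep$diffexpr <- de_section
  var_path <- file.path(out_dir, "pca_variance.tsv")
  rep$pca_variance <- if (file.exists(var_path)) read_tsv(var_path) else list()
  enr_path <- file.path(out_dir, "enrichment.tsv")
  rep$enrichment <- if (file.exists(enr_path)) {
    e <- read_tsv(enr_path)
    e[, setdiff(names(e), "leading_edge")]
  } else {
    list()
  }
  rates_path <- file.path(out_dir, "matching_rates.tsv")
  rep$matching_rates <- if (file.exists(rates_path) &&
                            file.size(rates_path) > 1) {
    read_tsv(rates_path)
  } else {
    list()
  }
  rep
}

format_report <- function(rep) {
  out <- c(sprintf("== %s ==", rep$generated_by), "")
  for (ct in names(rep$diffexpr)) {
    d <- rep$diffexpr[[ct]]
    out <- c(out, sprintf("-- %s --", ct),
             sprintf("%d of %d genes significant at p < %g (%.1f%%)",
                     d$n_significant, d$n_total, rep$alpha,
                     d$proportion_percent),
             "top genes:",
             utils::capture.output(print(as.data.frame(d$top_genes),
                                         row.names = FALSE)), "")
  }
  if (length(rep$pca_variance)) {
    out <- c(out, "-- PCA variance --",
             utils::capture.output(print(as.data.frame(rep$pca_variance)[
               seq_len(min(5, length(rep$pca_variance$component))), ],
               row.names = FALSE)), "")
  }
  if (length(rep$enrichment)) {
    out <- c(out, "-- enrichment --",
             utils::capture.output(print(as.data.frame(rep$enrichment),
                                         row.names = FALSE)), "")
  }
  if (length(rep$matching_rates)) {
    out <- c(out, "-- mutability matching rates --",
             utils::capture.output(print(as.data.frame(rep$matching_rates),
                                         row.names = FALSE)), "")
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: cnseq <subcommand> --config <config.json> [--out <dir>] [--seed <int>]",
    "subcommands: run simulate de pca cluster enrich mutability report",
    "  run        execute every enabled stage",
    "  <stage>    execute one stage (plus its input stages)",
    "  report     rebuild report.json/report.txt from --out",
    sep = "\n")
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      cn_abort(sprintf("unexpected argument '%s'", a), "cnseq_config_error")
    }
    key <- substring(a, 3)
    if (i == length(args)) {
      cn_abort(sprintf("missing value for --%s", key), "cnseq_config_error")
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`run`, `simulate`, `de`, `pca`,
#' `cluster`, `enrich`, `mutability`, `report`). Logs go to stderr;
#' results are only ever written to files. Returns (rather than calls
#' `quit()` with) the exit code: 0 on success, 2 for configuration
#' errors, 3 for stage failures.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return integer exit code, invisibly.
#' @export
cnseq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(invisible(0L))
  }
  sub <- args[1]
  known <- c("run", PIPELINE_STAGES)
  code <- tryCatch({
    if (!sub %in% known) {
      cn_abort(sprintf("unknown subcommand '%s'", sub), "cnseq_config_error")
    }
    opts <- parse_cli_opts(args[-1])
    if (sub == "report" && is.null(opts$config)) {
      if (is.null(opts$out)) {
        cn_abort("report needs --config or --out", "cnseq_config_error")
      }
      rep <- report_from_dir(opts$out)
      jsonlite::write_json(rep, file.path(opts$out, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      writeLines(format_report(rep), file.path(opts$out, "report.txt"))
      return(invisible(0L))
    }
    if (is.null(opts$config)) {
      cn_abort("--config is required", "cnseq_config_error")
    }
    cfg <- load_config(opts$config)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    stages <- if (sub == "run") NULL else sub
    run_pipeline(cfg, stages = stages)
    0L
  },
  cnseq_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    2L
  },
  cnseq_stage_error = function(e) {
    message("stage error: ", conditionMessage(e))
    3L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(code)
}
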