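test_that("simulate_fpkm is a pure function of spec + seed", {
  spec <- expression_sim_spec(n_genes = 100, seed = 5)
  a <- simulate_fpkm(spec)
  b <- simulate_fpkm(spec)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$metadata, b$metadata)
  c_ <- simulate_fpkm(expression_sim_spec(n_genes = 100, seed = 6))
  expect_false(identical(unclass(a$matrix), unclass(c_$matrix)))
  # cohort shape: 5 + 6 + 3 samples, two sessions, all values positive
  expect_equal(ncol(a$matrix), 14L)
  expect_equal(as.vector(table(a$metadata$group)[c("control", "AD", "PD")]),
               c(5L, 6L, 3L))
  expect_setequal(unique(a$metadata$batch), c("session1", "session2"))
  expect_true(all(unclass(a$matrix) > 0))
})

test_that("deterministic limit reproduces exact printed-style group means", {
  # zero noise, zero batch effect, constant baseline at 305 FPKM,
  # one gene spiked down by 305/46
  spec <- expression_sim_spec(
    n_genes = 3, group_sizes = c(control = 5L, PD = 3L),
    baseline_log_mean = log(305), baseline_log_sd = 0,
    spike_table = data.frame(gene_index = 1L, group = "PD",
                             fold = 305 / 46, direction = "down",
                             stringsAsFactors = FALSE),
    batch_effect_sd = 0, noise_log_sd = 0,
    outlier_control_index = NULL, seed = 1)
  sim <- simulate_fpkm(spec)
  ctrl <- sim$metadata$sample_id[sim$metadata$group == "control"]
  pd <- sim$metadata$sample_id[sim$metadata$group == "PD"]
  expect_equal(mean(unclass(sim$matrix)[1, ctrl]), 305, tolerance = 1e-9)
  expect_equal(mean(unclass(sim$matrix)[1, pd]), 46, tolerance = 1e-9)
  expect_equal(fold_change(305, mean(unclass(sim$matrix)[1, pd]))$fold,
               305 / 46, tolerance = 1e-9)
  # truth records carry the designed effect
  fold_rows <- sim$truth[sim$truth$property == "true_fold_PD", ]
  expect_true(any(fold_rows$entity == "G00001" &
                    abs(as.numeric(fold_rows$value) - 305 / 46) < 1e-12))
})

test_that("realized fold change of a 4x spike is unbiased within 10%", {
  folds <- vapply(1:500, function(i) {
    spec <- expression_sim_spec(
      n_genes = 5, baseline_log_mean = log(50), baseline_log_sd = 0.5,
      spike_table = data.frame(gene_index = 1L, group = "AD", fold = 4,
                               direction = "up", stringsAsFactors = FALSE),
      batch_effect_sd = 0, noise_log_sd = 0.4,
      outlier_control_index = NULL, seed = 10000 + i)
    sim <- simulate_fpkm(spec)
    ctrl <- sim$metadata$sample_id[sim$metadata$group == "control"]
    ad <- sim$metadata$sample_id[sim$metadata$group == "AD"]
    mean(unclass(sim$matrix)[1, ad]) / mean(unclass(sim$matrix)[1, ctrl])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 4) / 4, 0.10)
})

test_that("spike validation rejects out-of-range indices and bad folds", {
  expect_error(expression_sim_spec(
    n_genes = 10,
    spike_table = data.frame(gene_index = 11L, group = "AD", fold = 2,
                             direction = "up")),
    class = "cnseq_argument_error")
  expect_error(expression_sim_spec(
    n_genes = 10,
    spike_table = data.frame(gene_index = 1L, group = "AD", fold = 0.5,
                             direction = "up")),
    class = "cnseq_argument_error")
  expect_error(expression_sim_spec(n_genes = 10, outlier_control_index = 9L),
               class = "cnseq_argument_error")
})

test_that("the outlier control sample tracks the disease distribution", {
  spikes <- data.frame(gene_index = 1:40, group = "AD", fold = 6,
                       direction = "up", stringsAsFactors = FALSE)
  spec <- expression_sim_spec(n_genes = 200, spike_table = spikes,
                              outlier_control_index = 3L, seed = 2)
  sim <- simulate_fpkm(spec)
  lv <- log_transform(sim$matrix)
  spiked <- 1:40
  ctrl_cols <- paste0("control_", 1:5)
  outlier_mean <- mean(lv[spiked, "control_3"])
  other_ctrl <- mean(lv[spiked, setdiff(ctrl_cols, "control_3")])
  ad_mean <- mean(lv[spiked, paste0("AD_", 1:6)])
  expect_gt(outlier_mean, other_ctrl + 0.8 * log2(6) / 2)
  expect_lt(abs(outlier_mean - ad_mean), abs(outlier_mean - other_ctrl))
  # and it clusters with the disease samples
  hc <- hierarchical_cluster(lv)
  cut <- cutree(hc, 2)
  expect_equal(unname(cut[["control_3"]]), unname(cut[["AD_1"]]))
  expect_true(all(cut[setdiff(ctrl_cols, "control_3")] !=
                    cut[["AD_1"]]))
})

test_that("simulate_genome hits target distances exactly and A+T within tolerance", {
  spec <- genome_sim_spec(
    chromosomes = data.frame(name = c("chr1", "chr2"),
                             length_bp = c(400000, 300000)),
    placements = data.frame(
      gene_id = c("gA", "gB", "gC"),
      chromosome = c("chr1", "chr1", "chr2"),
      target_telomere_distance_mb = c(0.01, 0.15, 0.0),
      length_bp = c(100000, 20000, 5000),
      target_at_fraction = c(0.62, 0.40, 1.0),
      stringsAsFactors = FALSE),
    seed = 3)
  sim <- simulate_genome(spec)
  calls <- factor_calls(sim$loci, sim$chrom_info, sequences = sim$sequences)
  expect_equal(calls$telomere_distance_mb, c(0.01, 0.15, 0.0),
               tolerance = 1e-6 / 2)
  # realized distance within 1 bp of target by construction
  expect_true(all(abs(calls$telomere_distance_mb -
                        c(0.01, 0.15, 0.0)) * 1e6 <= 1))
  expect_true(abs(calls$at_fraction[1] - 0.62) <= 0.01)
  expect_true(abs(calls$at_fraction[2] - 0.40) <= 0.01)
  expect_equal(calls$at_fraction[3], 1.0)  # A/T-only boundary case

  # determinism
  sim2 <- simulate_genome(spec)
  expect_identical(as.character(sim$sequences$synthetic),
                   as.character(sim2$sequences$synthetic))
  # infeasible placement errors
  bad <- genome_sim_spec(
    chromosomes = data.frame(name = "c", length_bp = 1000),
    placements = data.frame(gene_id = "g", chromosome = "c",
                            target_telomere_distance_mb = 0.01,
                            length_bp = 999, target_at_fraction = 0.5))
  expect_error(simulate_genome(bad), "infeasible",
               class = "cnseq_argument_error")
})

test_that("genome round-trips through FASTA/GFF3 on disk", {
  spec <- genome_sim_spec(
    chromosomes = data.frame(name = "chr1", length_bp = 50000),
    placements = data.frame(gene_id = "gA", chromosome = "chr1",
                            target_telomere_distance_mb = 0.002,
                            length_bp = 3000, target_at_fraction = 0.7),
    seed = 9)
  sim <- simulate_genome(spec)
  dir <- file.path(tempdir(), "genome_rt")
  paths <- write_genome(sim, dir)
  ci <- read_chrom_lengths(paths$chrom_lengths)
  loci <- read_gene_loci(paths$gff3, "synthetic", ci)
  expect_equal(loci$start_bp, sim$loci$start_bp)
  expect_equal(loci$end_bp, sim$loci$end_bp)
  dna <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(as.character(dna[["chr1"]]),
               as.character(sim$sequences$synthetic[["chr1"]]))
})

test_that("simulate_gene_sets designates one enriched set with matching spikes", {
  base <- expression_sim_spec(n_genes = 500, seed = 4)
  gs <- simulate_gene_sets(n_sets = 5, set_size = 20, enriched_set_fold = 4,
                           matrix_spec = base, seed = 11)
  expect_length(gs$sets, 5)
  expect_equal(gs$truth$entity, "SET_01")
  spiked_ids <- sprintf("G%05d", unique(gs$spec$spike_table$gene_index))
  expect_setequal(gs$sets$SET_01$members, spiked_ids)
  # determinism and the null case
  gs2 <- simulate_gene_sets(5, 20, 4, base, seed = 11)
  expect_identical(lapply(gs$sets, `[[`, "members"),
                   lapply(gs2$sets, `[[`, "members"))
  null_gs <- simulate_gene_sets(5, 20, 1, base, seed = 11)
  expect_null(null_gs$spec$spike_table)
  expect_error(simulate_gene_sets(1, 20, 4, base),
               class = "cnseq_argument_error")
  expect_error(simulate_gene_sets(5, 501, 4, base),
               class = "cnseq_argument_error")
})
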