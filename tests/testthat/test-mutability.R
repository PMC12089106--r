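chrom_fixture <- function() {
  chromosome_info(data.frame(
    species = c("human", "human", "mouse"),
    chromosome = c("chr1", "chr2", "chr1"),
    length_bp = c(200e6, 100e6, 150e6), stringsAsFactors = FALSE))
}

test_that("telomere_distance takes the nearest end and respects bounds", {
  expect_equal(telomere_distance(10000001, 10100000, 200e6), 10)
  expect_equal(telomere_distance(1e6, 200e6, 200e6), 0)     # ends at last base
  expect_equal(telomere_distance(49.5e6 + 1, 50.5e6, 100e6), 49.5)
  # per-arm modes
  expect_equal(telomere_distance(10000001, 10100000, 200e6, arm = "q"), 189.9)
  # reflection invariance: [s, e] -> [L - e + 1, L - s + 1]
  set.seed(8)
  for (i in 1:25) {
    L <- sample.int(1e8, 1)
    s <- sample.int(L - 100, 1)
    e <- s + sample.int(min(100, L - s), 1)
    expect_equal(telomere_distance(s, e, L),
                 telomere_distance(L - e + 1, L - s + 1, L))
  }
  expect_error(telomere_distance(0, 10, 100),
               class = "cnseq_validation_error")
  expect_error(telomere_distance(5, 200, 100),
               class = "cnseq_validation_error")
})

test_that("factor thresholds are strict and monotone", {
  expect_false(classify_f_i(60))
  expect_true(classify_f_i(10))
  expect_false(classify_f_i(50))          # boundary falls outside
  expect_error(classify_f_i(-1), class = "cnseq_argument_error")
  # monotone in threshold: raising it never turns TRUE into FALSE
  d <- c(0, 10, 49.99, 50, 80)
  lo <- classify_f_i(d, 50)
  hi <- classify_f_i(d, 60)
  expect_true(all(hi[lo]))

  expect_true(classify_f_ii(0.62))
  expect_false(classify_f_ii(0.59))       # boundary falls outside
  expect_false(classify_f_ii(0.50))
  expect_error(classify_f_ii(1.2), class = "cnseq_argument_error")
})

test_that("at_content counts unambiguous bases only", {
  expect_equal(at_content("AATT"), 1)
  expect_equal(at_content("ACGT"), 0.5)
  expect_equal(at_content("ACGTN"), 0.5)
  expect_equal(at_content("acgt"), 0.5)
  expect_error(at_content("NNN"), class = "cnseq_argument_error")
  expect_error(at_content(""), class = "cnseq_argument_error")
  # complement-swap symmetry: relabeling A<->C and T<->G flips the fraction
  set.seed(3)
  seqs <- replicate(10, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                              collapse = ""))
  for (s in seqs) {
    swapped <- chartr("ACTG", "CAGT", s)  # A<->C, T<->G relabeling
    expect_equal(at_content(swapped), 1 - at_content(s))
  }
})

test_that("matching_rate counts panel genes per species and factor", {
  calls <- data.frame(
    gene_id = paste0("g", 1:10), species = "human",
    telomere_distance_mb = c(rep(10, 7), rep(60, 3)),
    f_i = c(rep(TRUE, 7), rep(FALSE, 3)),
    at_fraction = 0.5, f_ii = FALSE, stringsAsFactors = FALSE)
  mr <- matching_rate(calls, "human", "f_i")
  expect_equal(mr$rate_percent, 70)
  expect_equal(mr$n_genes, 10)
  expect_equal(mr$n_matching, 7)
  calls$f_i <- FALSE
  expect_equal(matching_rate(calls, "human", "f_i")$rate_percent, 0)
  calls$f_i <- TRUE
  expect_equal(matching_rate(calls, "human", "f_i")$rate_percent, 100)
  # brute-force equality on a random fixture
  set.seed(12)
  calls$f_ii <- sample(c(TRUE, FALSE), 10, TRUE)
  expect_equal(matching_rate(calls, "human", "f_ii")$rate_exact,
               100 * sum(calls$f_ii) / 10)
  expect_error(matching_rate(calls, "rat", "f_i"),
               class = "cnseq_argument_error")
})

test_that("linkage rules use the inclusive 50 cM boundary and 1 cM = 1 Mb", {
  expect_equal(linkage_status(50), "linked")
  expect_equal(linkage_status(51), "unlinked")
  expect_equal(linkage_status(0), "linked")
  expect_error(linkage_status(-2), class = "cnseq_argument_error")
  expect_equal(cm_to_mb(1), 1)
  expect_equal(cm_to_mb(0), 0)
  expect_equal(cm_to_mb(50), 50)
  expect_error(cm_to_mb(-1), class = "cnseq_argument_error")
})

test_that("size_conservation flags lengths against the reference range", {
  ref <- reference_size_range(1000, 8000, "ad_pd_panel")
  rec <- data.frame(species = c("mouse", "rat", "chimpanzee", "human"),
                    transcript_length_bp = c(3000, 3100, 2900, 3050),
                    stringsAsFactors = FALSE)
  sc <- size_conservation(rec, ref)
  expect_true(all(sc$flags$flag == "typical"))
  expect_equal(sc$length_ratio, 3100 / 2900, tolerance = 1e-12)

  rec$transcript_length_bp[4] <- 16000  # elongated human transcript
  sc2 <- size_conservation(rec, ref)
  expect_equal(sc2$flags$flag[4], "unusual")
  expect_equal(sum(sc2$flags$flag == "unusual"), 1L)

  rec3 <- rec
  rec3$transcript_length_bp <- rep(4000, 4)
  sc3 <- size_conservation(rec3, ref)
  expect_equal(sc3$length_ratio, 1)
  expect_true(all(sc3$flags$flag == "typical"))

  expect_error(size_conservation(rec[1, ], ref),
               class = "cnseq_argument_error")
})

test_that("gene_loci validates against chromosome bounds", {
  ci <- chrom_fixture()
  ok <- gene_loci(data.frame(species = "human", gene_id = "OPRM1",
                             chromosome = "chr1", start_bp = 1e6,
                             end_bp = 2e6, stringsAsFactors = FALSE), ci)
  expect_s3_class(ok, "GeneLocusTable")
  expect_error(gene_loci(data.frame(species = "human", gene_id = "x",
                                    chromosome = "chrZ", start_bp = 1,
                                    end_bp = 10), ci),
               class = "cnseq_validation_error")
  expect_error(gene_loci(data.frame(species = "human", gene_id = "x",
                                    chromosome = "chr2", start_bp = 1,
                                    end_bp = 150e6), ci),
               "beyond", class = "cnseq_validation_error")
})

test_that("factor_calls integrates distances and sequence composition", {
  ci <- chromosome_info(data.frame(species = "human", chromosome = "chrT",
                                   length_bp = 2000, stringsAsFactors = FALSE))
  seq_chr <- paste(c(rep("A", 500), rep("G", 1500)), collapse = "")
  loci <- gene_loci(data.frame(
    species = "human", gene_id = c("near_at", "far_gc"),
    chromosome = "chrT", start_bp = c(101, 901), end_bp = c(300, 1300),
    stringsAsFactors = FALSE), ci)
  seqs <- list(human = Biostrings::DNAStringSet(c(chrT = seq_chr)))
  calls <- factor_calls(loci, ci, sequences = seqs,
                        threshold_mb = 0.0005, threshold_at = 0.59)
  expect_equal(calls$telomere_distance_mb, c(100 / 1e6, 700 / 1e6))
  expect_equal(calls$f_i, c(TRUE, FALSE))
  expect_equal(calls$at_fraction, c(1, 0))
  expect_equal(calls$f_ii, c(TRUE, FALSE))

  # FASTA/length-table disagreement is an error
  ci_bad <- chromosome_info(data.frame(species = "human",
                                       chromosome = "chrT",
                                       length_bp = 1999,
                                       stringsAsFactors = FALSE))
  loci_bad <- gene_loci(data.frame(species = "human", gene_id = "g",
                                   chromosome = "chrT", start_bp = 1,
                                   end_bp = 10, stringsAsFactors = FALSE),
                        ci_bad)
  expect_error(factor_calls(loci_bad, ci_bad, sequences = seqs),
               "disagree", class = "cnseq_validation_error")
})

test_that("loci read from GFF3 and BED with coordinate conventions", {
  ci <- chromosome_info(data.frame(species = "synthetic",
                                   chromosome = "chr1", length_bp = 10000,
                                   stringsAsFactors = FALSE))
  gff <- withr_local_tempfile(".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tcnseq\tgene\t101\t300\t.\t+\t.\tID=gA;gene_id=gA",
               "chr1\tcnseq\tgene\t501\t800\t.\t-\t.\tID=gB;gene_id=gB"),
             gff)
  loci <- read_gene_loci(gff, "synthetic", ci)
  expect_equal(loci$start_bp, c(101, 501))
  expect_equal(loci$end_bp, c(300, 800))

  bed <- withr_local_tempfile(".bed")
  writeLines(c("chr1\t100\t300\tgA\t0\t+", "chr1\t500\t800\tgB\t0\t-"), bed)
  loci_bed <- read_gene_loci(bed, "synthetic", ci)
  # BED is 0-based half-open: same genes as the GFF3 above
  expect_equal(loci_bed$start_bp, loci$start_bp)
  expect_equal(loci_bed$end_bp, loci$end_bp)
})
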