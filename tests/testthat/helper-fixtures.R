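# Shared fixture builders: everything is generated in code, nothing is
# stored on disk.

make_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / 2, byrow = TRUE)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  ExpressionMatrix(m, gene_ids = genes, sample_ids = samples)
}

make_meta <- function(groups, batches = NULL) {
  ids <- paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                        FUN = seq_along))
  if (is.null(batches)) batches <- rep("session1", length(groups))
  SampleMetadata(data.frame(sample_id = ids, group = groups, batch = batches,
                            stringsAsFactors = FALSE))
}

# Matrix + metadata for an n-control vs n-AD toy cohort with gene-major
# values supplied per row.
toy_cohort <- function(values_by_gene, n_control, n_ad) {
  ng <- length(values_by_gene)
  m <- do.call(rbind, values_by_gene)
  groups <- c(rep("control", n_control), rep("AD", n_ad))
  ids <- c(paste0("control_", seq_len(n_control)), paste0("AD_", seq_len(n_ad)))
  em <- ExpressionMatrix(m, gene_ids = paste0("g", seq_len(ng)),
                         sample_ids = ids)
  meta <- SampleMetadata(data.frame(sample_id = ids, group = groups,
                                    batch = "session1",
                                    stringsAsFactors = FALSE))
  list(m = em, meta = meta)
}

write_tmp_tsv <- function(lines) {
  path <- withr_local_tempfile()
  writeLines(lines, path)
  path
}

# minimal local tempfile helper (no withr dependency): cleaned up by the
# session temp dir.
withr_local_tempfile <- function(ext = ".tsv") {
  tempfile(fileext = ext)
}

# Brute-force Mann-Whitney oracle: enumerate all label assignments,
# computing U by explicit pair counting (independent of the package's
# rank-sum implementation).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  splits <- utils::combn(n, nx)
  u_null <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(x, y)
  min(1, 2 * min(mean(u_null <= u_obs + 1e-9), mean(u_null >= u_obs - 1e-9)))
}

# Unweighted KS oracle for the running-sum enrichment score: signed
# maximum deviation between the hit and miss empirical CDFs.
oracle_ks_es <- function(ids, members) {
  hit <- ids %in% members
  n <- length(ids)
  nh <- sum(hit)
  p_hit <- cumsum(hit) / nh
  p_miss <- if (nh < n) cumsum(!hit) / (n - nh) else rep(0, n)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}
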