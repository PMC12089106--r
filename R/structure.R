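#' Principal component analysis with genes as observations
#'
#' Eigen-decomposes the sample-by-sample covariance (or, when
#' `standardize = TRUE`, correlation) matrix of an expression matrix in
#' which genes are the observations and samples the variables, matching
#' the biplot convention where individual genes (e.g. FKBP5, MT-ATP6P1)
#' are datapoints with scores and samples carry loadings. Signs are fixed
#' deterministically: for every component, the largest-magnitude sample
#' loading is made positive.
#'
#' @param m an [ExpressionMatrix] or plain numeric matrix (genes x
#'   samples); typically `log2(FPKM + 1)` values.
#' @param standardize scale each sample column to unit variance
#'   (correlation PCA, the default).
#' @return list of class `PCAResult` with `scores` (gene x component),
#'   `loadings` (sample x component), `sdev`, `variance_proportion`
#'   (sums to 1) and `n_components`.
#' @export
pca_expression <- function(m, standardize = TRUE) {
  vals <- unclass(m)
  if (!is.matrix(vals) || !is.numeric(vals)) {
    abort_argument("`m` must be a numeric matrix")
  }
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    abort_argument("PCA requires >= 2 genes and >= 2 samples")
  }
  sds <- apply(vals, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    abort_validation(sprintf(
      "constant sample column(s) under standardization: %s",
      paste(colnames(vals)[sds == 0], collapse = ", ")))
  }
  fit <- stats::prcomp(vals, center = TRUE, scale. = standardize)
  # deterministic sign convention
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  var_prop <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation, sdev = fit$sdev,
                 center = fit$center, scale = fit$scale,
                 variance_proportion = var_prop,
                 n_components = length(fit$sdev)),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  k <- min(5L, x$n_components)
  cat(sprintf("PCAResult: %d components over %d samples\n",
              x$n_components, nrow(x$loadings)))
  cat("variance proportion:",
      paste(sprintf("PC%d=%.1f%%", seq_len(k),
                    100 * x$variance_proportion[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

expr_dist <- function(x, metric) {
  switch(metric,
    euclidean = stats::dist(x, method = "euclidean"),
    manhattan = stats::dist(x, method = "manhattan"),
    correlation = stats::as.dist(1 - stats::cor(t(x))),
    abort_argument(sprintf("unknown metric '%s'", metric))
  )
}

linkage_method <- function(linkage) {
  switch(linkage,
    ward = "ward.D2",
    average = "average",
    single = "single",
    complete = "complete",
    abort_argument(sprintf("unknown linkage '%s'", linkage))
  )
}

#' Hierarchically cluster samples on their gene expression profiles
#'
#' @param m an [ExpressionMatrix] or numeric matrix (genes x samples);
#'   typically log-transformed.
#' @param metric `"euclidean"` (default), `"manhattan"` or
#'   `"correlation"` (1 - Pearson).
#' @param linkage `"ward"` (default, Ward.D2), `"average"`, `"single"` or
#'   `"complete"`.
#' @return an `hclust` object over the samples (leaf labels are sample
#'   identifiers); serialize with [dendrogram_newick()].
#' @export
hierarchical_cluster <- function(m, metric = "euclidean", linkage = "ward") {
  vals <- unclass(m)
  if (ncol(vals) < 2L) abort_argument("need >= 2 samples to cluster")
  d <- expr_dist(t(vals), metric)
  stats::hclust(d, method = linkage_method(linkage))
}

#' Serialize a dendrogram to Newick
#'
#' Converts an `hclust` tree to `phylo` and writes Newick text with
#' branch lengths derived from the merge heights.
#'
#' @param hc an `hclust` object.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!inherits(hc, "hclust")) abort_argument("`hc` must be an hclust object")
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Partition genes into k expression subgroups
#'
#' Builds a gene-wise hierarchy (average linkage by default, mirroring the
#' subgroup profiles of cluster plots C(1)..C(k)) and cuts it into `k`
#' clusters; alternatively runs seeded k-means. Each cluster's mean
#' expression per sample is returned as its profile.
#'
#' @param m an [ExpressionMatrix] or numeric matrix (genes x samples).
#' @param k number of clusters, `1 <= k <=` gene count.
#' @param seed integer seed (used by the k-means method; the tree cut is
#'   deterministic).
#' @param method `"hclust"` (default) or `"kmeans"`.
#' @param metric,linkage dissimilarity and linkage for the gene tree.
#' @return list of class `GeneClusterResult` with `assignments`
#'   (data.frame `gene_id`, `cluster`) and `profiles` (k x samples matrix
#'   of cluster mean expression).
#' @export
gene_clusters <- function(m, k, seed = 1L, method = c("hclust", "kmeans"),
                          metric = "euclidean", linkage = "average") {
  method <- match.arg(method)
  vals <- unclass(m)
  if (!is_count(k) || k < 1L) abort_argument("`k` must be a positive integer")
  if (k > nrow(vals)) abort_argument("`k` exceeds the number of genes")
  cl <- if (method == "hclust") {
    hc <- stats::hclust(expr_dist(vals, metric), method = linkage_method(linkage))
    stats::cutree(hc, k = k)
  } else {
    with_seed(seed, stats::kmeans(vals, centers = k, nstart = 10L)$cluster)
  }
  profiles <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(vals[cl == j, , drop = FALSE])
  }))
  rownames(profiles) <- paste0("C", seq_len(k))
  structure(list(
    assignments = data.frame(gene_id = rownames(vals), cluster = unname(cl),
                             stringsAsFactors = FALSE),
    profiles = profiles, k = k, method = method),
    class = "GeneClusterResult")
}
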