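#' Fold change between two group means
#'
#' Computes the fold change `max(a, b) / min(a, b)` between two mean FPKM
#' values, with `mean_a` taken as the reference (control) group. The
#' direction describes group b relative to the reference. A zero mean in
#' the denominator yields an undefined-fold flag (`fold = NA`) rather than
#' an infinite value; two zero means are an error.
#'
#' @param mean_a reference-group mean FPKM (non-negative).
#' @param mean_b comparison-group mean FPKM (non-negative).
#' @return list with `fold` (>= 1, or `NA` when undefined), `direction`
#'   (`"up"`, `"down"` or `"unchanged"`, b relative to a), and `undefined`
#'   (logical).
#' @examples
#' fold_change(305, 46) # ~6.63-fold decrease
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is_scalar_number(mean_a) || !is_scalar_number(mean_b)) {
    abort_argument("group means must be single finite numbers")
  }
  if (mean_a < 0 || mean_b < 0) {
    abort_argument("group means must be non-negative")
  }
  if (mean_a == 0 && mean_b == 0) {
    cn_abort("fold change undefined: both group means are zero",
             "cnseq_undefined_fold_error")
  }
  direction <- if (mean_b > mean_a) "up" else if (mean_b < mean_a) "down" else "unchanged"
  if (min(mean_a, mean_b) == 0) {
    return(list(fold = NA_real_, direction = direction, undefined = TRUE))
  }
  list(fold = max(mean_a, mean_b) / min(mean_a, mean_b),
       direction = direction, undefined = FALSE)
}

# U statistic for x relative to y (number of x > y pairs, ties count 1/2),
# via the rank-sum identity.
mw_u_statistic <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

# Exact two-sided p by full enumeration of all C(nx+ny, nx) label splits.
mw_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  if (n > 20L) abort_argument("exact enumeration limited to nx + ny <= 20")
  r <- rank(pooled)
  splits <- utils::combn(n, nx)
  u_null <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
  u_obs <- mw_u_statistic(x, y)
  eps <- 1e-9
  p_lo <- mean(u_null <= u_obs + eps)
  p_hi <- mean(u_null >= u_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation with tie correction and continuity correction.
mw_approx_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  u <- mw_u_statistic(x, y)
  mu <- nx * ny / 2
  tab <- table(c(x, y))
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  cc <- if (u == mu) 0 else 0.5 * sign(u - mu)
  z <- (u - mu - cc) / sqrt(sigma2)
  max(min(2 * stats::pnorm(-abs(z)), 1), .Machine$double.xmin)
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' Two-sided rank-sum test for two independent samples. In `"auto"` mode
#' the full exact permutation distribution is enumerated when
#' `length(x) + length(y) <= 12` and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections is used. The
#' two-sided p-value is `min(1, 2 * smaller one-sided tail)`.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` (forced enumeration, combined n <= 20)
#'   or `"approx"`.
#' @return list with `U` (statistic for `x` relative to `y`) and
#'   `p_two_sided` in (0, 1].
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort_argument("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort_argument("samples must not contain NA")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = (length(x) + length(y) <= 12L) && !ties
  )
  p <- if (use_exact) mw_exact_p(x, y) else mw_approx_p(x, y)
  list(U = mw_u_statistic(x, y), p_two_sided = p)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; the default two-group test for FPKM group means.
#'
#' @param x,y numeric samples, each with at least two values and nonzero
#'   variance.
#' @return list with `t`, `df` and `p_two_sided`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L) abort_argument("group x needs at least 2 values")
  if (length(y) < 2L) abort_argument("group y needs at least 2 values")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0) abort_argument("degenerate (zero) variance in group x")
  if (vy == 0) abort_argument("degenerate (zero) variance in group y")
  nx <- length(x)
  ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p_two_sided = 2 * stats::pt(-abs(t), df))
}

#' Heteroscedasticity-robust three-group ANOVA with control-referenced
#' post-hoc comparisons
#'
#' Computes the Welch ANOVA and the Brown-Forsythe F* omnibus tests over
#' three or more groups, then control-referenced pairwise Welch
#' comparisons adjusted in the Dunnett-T3 style: the studentized maximum
#' modulus is approximated under independence, which reduces to a Sidak
#' step over the pairwise Welch p-values. Games-Howell (studentized range)
#' adjustment is available as an option.
#'
#' @param groups named list of numeric vectors, one per group; at least 3
#'   groups with >= 2 values and nonzero variance each.
#' @param reference name of the reference group (default `"control"`; must
#'   be present in `names(groups)`).
#' @param posthoc `"dunnett-t3"` (default) or `"games-howell"`.
#' @return list with `welch_p`, `brown_forsythe_p`, `p_omnibus` (the Welch
#'   p), and `per_comparison`, a named numeric vector of adjusted p-values
#'   for each `<group>-vs-<reference>` contrast.
#' @export
bf_welch_anova <- function(groups, reference = "control",
                           posthoc = c("dunnett-t3", "games-howell")) {
  posthoc <- match.arg(posthoc)
  if (!is.list(groups) || length(groups) < 3L) {
    abort_argument("need >= 3 groups; use welch_t()/mann_whitney_u() for two")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort_argument("`groups` must be a named list")
  }
  for (g in names(groups)) {
    v <- groups[[g]]
    if (length(v) < 2L) abort_argument(sprintf("group '%s' needs >= 2 values", g))
    if (stats::var(v) == 0) {
      abort_argument(sprintf("degenerate (zero) variance in group '%s'", g))
    }
  }
  if (!reference %in% names(groups)) {
    abort_argument(sprintf("reference group '%s' not found", reference))
  }
  k <- length(groups)
  ni <- vapply(groups, length, integer(1))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  n_tot <- sum(ni)

  # Welch ANOVA
  wi <- ni / vi
  w <- sum(wi)
  mw <- sum(wi * mi) / w
  a <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / w)^2 / (ni - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f_welch <- a / b
  df2_welch <- (k^2 - 1) / (3 * lambda)
  welch_p <- stats::pf(f_welch, k - 1, df2_welch, lower.tail = FALSE)

  # Brown-Forsythe F* for equality of means
  grand <- sum(ni * mi) / n_tot
  denom_terms <- (1 - ni / n_tot) * vi
  f_bf <- sum(ni * (mi - grand)^2) / sum(denom_terms)
  ci <- denom_terms / sum(denom_terms)
  df2_bf <- 1 / sum(ci^2 / (ni - 1))
  bf_p <- stats::pf(f_bf, k - 1, df2_bf, lower.tail = FALSE)

  others <- setdiff(names(groups), reference)
  n_cmp <- length(others)
  per <- vapply(others, function(g) {
    wt <- welch_t(groups[[g]], groups[[reference]])
    if (posthoc == "dunnett-t3") {
      # SMM under independence: P(max |T| > t) = 1 - (2F(t) - 1)^k
      min(1, 1 - (1 - wt$p_two_sided)^n_cmp)
    } else {
      stats::ptukey(sqrt(2) * abs(wt$t), nmeans = k, df = wt$df,
                    lower.tail = FALSE)
    }
  }, numeric(1))
  names(per) <- paste0(others, "-vs-", reference)

  list(welch_p = welch_p, brown_forsythe_p = bf_p, p_omnibus = welch_p,
       per_comparison = per)
}

#' Significance star labels
#'
#' Standard notation: `""` for p >= 0.05, `"*"` for p < 0.05, `"**"` for
#' p < 0.01 and `"***"` for p < 0.005, all thresholds strict.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` maps to `""`).
#' @return character vector of star labels.
#' @export
star_label <- function(p) {
  if (!is.numeric(p)) abort_argument("`p` must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort_argument("p-values must lie in [0, 1]")
  }
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.005] <- "***"
  out
}

#' Proportion of significant tests
#'
#' Counts p-values strictly below `alpha` and reports their percentage of
#' the total (e.g. 2,144 of 62,704 loci gives 3.4%).
#'
#' @param p_values numeric vector of p-values (`NA` entries count toward
#'   the total but never as significant).
#' @param alpha significance level in (0, 1).
#' @return list of class `SignificanceSummary` with `n_total`,
#'   `n_significant`, `alpha` and `proportion_percent` (exact; the print
#'   method rounds to one decimal).
#' @export
significance_summary <- function(p_values, alpha = 0.05) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_argument("`alpha` must lie in (0, 1)")
  }
  n_total <- length(p_values)
  n_sig <- sum(!is.na(p_values) & p_values < alpha)
  structure(list(n_total = n_total, n_significant = n_sig, alpha = alpha,
                 proportion_percent = if (n_total) 100 * n_sig / n_total else 0),
            class = "SignificanceSummary")
}

#' @export
print.SignificanceSummary <- function(x, ...) {
  cat(sprintf("%d of %d tests significant at p < %g (%.1f%%)\n",
              x$n_significant, x$n_total, x$alpha,
              round(x$proportion_percent, 1)))
  invisible(x)
}

parse_contrast <- function(contrast) {
  parts <- strsplit(contrast, "-vs-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    abort_argument(sprintf("contrast '%s' must have the form '<group>-vs-<reference>'",
                           contrast))
  }
  list(b = parts[1], a = parts[2])
}

#' Per-gene group comparison over a contrast
#'
#' For every gene, computes reference and comparison group means on the
#' raw FPKM scale, the fold change with direction, the chosen two-group
#' test and its star label. Genes where the test is degenerate (e.g. zero
#' variance for Welch) receive `NA` p-values rather than failing the run.
#'
#' @param m an [ExpressionMatrix] of raw FPKM values.
#' @param meta a `SampleMetadata` data.frame covering all samples.
#' @param contrast contrast label of the form `"<group>-vs-<reference>"`,
#'   e.g. `"AD-vs-control"`.
#' @param test `"welch"` (default) or `"mann-whitney"`.
#' @param mw_mode mode passed to [mann_whitney_u()].
#' @param p_adjust `"none"` (default; raw p-values are reported) or
#'   `"BH"` to add a Benjamini-Hochberg adjusted column as an extension.
#' @return data.frame of class `GroupComparisonTable` with one row per
#'   gene: `gene_id`, `contrast`, `mean_a`, `mean_b`, `fold_change`,
#'   `direction`, `test_name`, `statistic`, `p_value`, `star_label` (and
#'   `p_adjusted` when requested).
#' @export
compare_groups <- function(m, meta, contrast, test = c("welch", "mann-whitney"),
                           mw_mode = "auto", p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(m, "ExpressionMatrix"))
  validate_samples(m, meta)
  cdef <- parse_contrast(contrast)
  sa <- meta$sample_id[meta$group == cdef$a]
  sb <- meta$sample_id[meta$group == cdef$b]
  sa <- intersect(sa, sample_ids(m))
  sb <- intersect(sb, sample_ids(m))
  if (!length(sa)) abort_argument(sprintf("no samples in reference group '%s'", cdef$a))
  if (!length(sb)) abort_argument(sprintf("no samples in group '%s'", cdef$b))

  vals <- unclass(m)
  ng <- nrow(vals)
  mean_a <- rowMeans(vals[, sa, drop = FALSE])
  mean_b <- rowMeans(vals[, sb, drop = FALSE])
  fold <- rep(NA_real_, ng)
  direction <- rep("unchanged", ng)
  statistic <- rep(NA_real_, ng)
  p_value <- rep(NA_real_, ng)
  for (i in seq_len(ng)) {
    fc <- tryCatch(fold_change(mean_a[i], mean_b[i]), cnseq_error = function(e) NULL)
    if (!is.null(fc)) {
      fold[i] <- fc$fold
      direction[i] <- fc$direction
    }
    res <- tryCatch(
      if (test == "welch") {
        wt <- welch_t(vals[i, sb], vals[i, sa])
        c(wt$t, wt$p_two_sided)
      } else {
        mw <- mann_whitney_u(vals[i, sb], vals[i, sa], mode = mw_mode)
        c(mw$U, mw$p_two_sided)
      },
      cnseq_error = function(e) c(NA_real_, NA_real_)
    )
    statistic[i] <- res[1]
    p_value[i] <- res[2]
  }
  out <- data.frame(
    gene_id = gene_ids(m), contrast = contrast,
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fold, direction = direction,
    test_name = if (test == "welch") "welch_t" else "mann_whitney_u",
    statistic = statistic, p_value = p_value,
    star_label = star_label(p_value),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (p_adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  class(out) <- c("GroupComparisonTable", "data.frame")
  out
}

#' Rank genes by p-value and effect size
#'
#' Stable sort: ascending p-value, ties broken by descending fold change,
#' remaining ties by gene identifier. Genes with `NA` p-values sort last.
#'
#' @param results a `GroupComparisonTable` (see [compare_groups()]).
#' @return the same table sorted, with a 1-based `rank` column; class
#'   `RankedTable`.
#' @export
rank_genes <- function(results) {
  need <- c("gene_id", "p_value", "fold_change")
  if (!all(need %in% names(results))) {
    abort_argument("`results` must carry gene_id, p_value and fold_change")
  }
  fc <- results$fold_change
  fc[is.na(fc)] <- -Inf
  ord <- order(results$p_value, -fc, results$gene_id,
               na.last = TRUE, method = "radix")
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- unique(c("RankedTable", class(results)))
  out
}

#' Write a ranked differential-expression table to TSV
#'
#' @param ranked a `RankedTable` from [rank_genes()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(ranked, path) {
  write_tsv(as.data.frame(ranked), path)
}
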