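test_that("fold_change matches the worked examples and guards zeros", {
  fc <- fold_change(305, 46)
  expect_equal(fc$fold, 305 / 46, tolerance = 1e-12)
  expect_equal(round(fc$fold, 2), 6.63)
  expect_equal(round(fc$fold), 7)
  expect_equal(fc$direction, "down")

  fc2 <- fold_change(305, 35)
  expect_equal(round(fc2$fold, 2), 8.71)
  expect_equal(fc2$direction, "down")

  fc3 <- fold_change(5, 5)
  expect_equal(fc3$fold, 1)
  expect_equal(fc3$direction, "unchanged")

  expect_error(fold_change(0, 0), class = "cnseq_undefined_fold_error")
  expect_error(fold_change(-1, 2), class = "cnseq_argument_error")
  z <- fold_change(0, 10)
  expect_true(z$undefined)
  expect_true(is.na(z$fold))
  expect_equal(z$direction, "up")
})

test_that("exact Mann-Whitney p equals brute-force enumeration (n_x+n_y <= 10)", {
  set.seed(42)
  for (nx in 1:5) {
    for (ny in nx:(10 - nx)) {
      if (ny < 1) next
      x <- rnorm(nx)
      y <- rnorm(ny)
      got <- mann_whitney_u(x, y, mode = "exact")
      expect_equal(got$p_two_sided, oracle_mw_p(x, y), tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Mann-Whitney handles separation, identity and mode switching", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_two_sided, 0.1)  # 2/choose(6,3)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)

  # exact vs normal approximation agree within 0.02 at n = 6 vs 6
  set.seed(7)
  x <- rnorm(6)
  y <- rnorm(6)
  pe <- mann_whitney_u(x, y, mode = "exact")$p_two_sided
  pa <- mann_whitney_u(x, y, mode = "approx")$p_two_sided
  expect_lt(abs(pe - pa), 0.02)

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "cnseq_argument_error")
})

test_that("welch_t matches stats::t.test and is antisymmetric", {
  set.seed(3)
  x <- rnorm(5, 1)
  y <- rnorm(7)
  got <- welch_t(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)

  strong <- welch_t(c(0, 0, 1), c(10, 11, 12))
  expect_lt(strong$p_two_sided, 0.01)

  swapped <- welch_t(y, x)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p_two_sided, got$p_two_sided)

  expect_error(welch_t(c(1, 1), c(1, 2)), "group x",
               class = "cnseq_argument_error")
})

test_that("bf_welch_anova: omnibus oracle, null case, adjustment monotone", {
  g <- list(control = c(0.1, 0.4, 1.1), AD = c(0.2, 1.0, 1.4),
            PD = c(10, 11, 12.5))
  res <- bf_welch_anova(g)
  # Welch omnibus agrees with stats::oneway.test
  vals <- unlist(g)
  fac <- factor(rep(names(g), lengths(g)))
  ref <- oneway.test(vals ~ fac, var.equal = FALSE)
  expect_equal(res$welch_p, ref$p.value, tolerance = 1e-10)
  expect_lt(res$per_comparison[["PD-vs-control"]], 0.05)

  # identical groups: no effect anywhere
  null_res <- bf_welch_anova(list(control = c(1, 2, 3), AD = c(1, 2, 3),
                                  PD = c(1, 2, 3)))
  expect_equal(null_res$welch_p, 1)
  expect_equal(null_res$brown_forsythe_p, 1)
  expect_true(all(null_res$per_comparison == 1))

  # adjusted p >= unadjusted pairwise Welch p
  for (grp in c("AD", "PD")) {
    un <- welch_t(g[[grp]], g$control)$p_two_sided
    expect_gte(res$per_comparison[[paste0(grp, "-vs-control")]], un)
  }

  expect_error(bf_welch_anova(list(a = 1:3, b = 1:3)),
               class = "cnseq_argument_error")
  # Games-Howell option returns valid probabilities
  gh <- bf_welch_anova(g, posthoc = "games-howell")
  expect_true(all(gh$per_comparison >= 0 & gh$per_comparison <= 1))
})

test_that("star_label is a strict step function at 0.05/0.01/0.005", {
  expect_equal(star_label(c(0.03, 0.0049, 0.05, 0.01, 0.005, 0.9, 1e-6)),
               c("*", "***", "", "*", "**", "", "***"))
  expect_equal(star_label(0.009), "**")
  expect_error(star_label(1.2), class = "cnseq_argument_error")
  expect_error(star_label(-0.1), class = "cnseq_argument_error")
  # consistency with significance_summary at each threshold
  set.seed(9)
  p <- runif(500)
  stars <- star_label(p)
  for (thr in c(0.05, 0.01, 0.005)) {
    expect_equal(significance_summary(p, thr)$n_significant,
                 sum(stars %in% c("*", "**", "***")[
                   c(0.05, 0.01, 0.005) <= thr]))
  }
})

test_that("significance_summary reproduces the cohort proportion", {
  p <- c(rep(0.049, 2144), rep(0.5, 62704 - 2144))
  s <- significance_summary(p, 0.05)
  expect_equal(s$n_significant, 2144)
  expect_equal(s$n_total, 62704)
  expect_equal(round(s$proportion_percent, 1), 3.4)

  expect_equal(significance_summary(rep(1, 10))$n_significant, 0)
  expect_equal(significance_summary(rep(0, 10))$proportion_percent, 100)
  expect_error(significance_summary(0.5, alpha = 1),
               class = "cnseq_argument_error")
})

test_that("rank_genes sorts by p then fold change then id, deterministically", {
  tbl <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    p_value = c(0.01, 0.001, 0.01, 0.01, 0.001),
    fold_change = c(2, 1.1, 3, 3, 1.1),
    stringsAsFactors = FALSE)
  r <- rank_genes(tbl)
  expect_equal(r$gene_id, c("g2", "g5", "g3", "g4", "g1"))
  expect_equal(r$rank, 1:5)
  # permutation of input, bit-identical across runs
  expect_setequal(r$gene_id, tbl$gene_id)
  expect_identical(rank_genes(tbl), r)
})

test_that("compare_groups drives per-gene statistics end to end", {
  fix <- toy_cohort(list(c(300, 310, 305, 40, 50, 45, 44),
                         c(5, 6, 5.5, 5.2, 6.1, 5.4, 5.9),
                         c(0, 0, 0, 3, 4, 5, 6)),
                    n_control = 3, n_ad = 4)
  res <- compare_groups(fix$m, fix$meta, "AD-vs-control")
  expect_s3_class(res, "GroupComparisonTable")
  expect_equal(res$mean_a[1], mean(c(300, 310, 305)))
  expect_equal(res$direction[1], "down")
  expect_lt(res$p_value[1], 0.05)
  expect_equal(res$star_label[1], star_label(res$p_value[1]))
  # gene 3: control mean is zero -> undefined fold, Welch degenerate -> NA p
  expect_true(is.na(res$fold_change[3]))
  expect_true(is.na(res$p_value[3]))

  mw <- compare_groups(fix$m, fix$meta, "AD-vs-control", test = "mann-whitney")
  expect_equal(unique(mw$test_name), "mann_whitney_u")
  expect_lt(mw$p_value[1], 0.1)

  expect_error(compare_groups(fix$m, fix$meta, "PD-vs-control"),
               class = "cnseq_argument_error")
  expect_error(compare_groups(fix$m, fix$meta, "badlabel"),
               class = "cnseq_argument_error")
})

test_that("type-I error matches the achievable size at n = (5, 6)", {
  # achievable size of the exact test from the enumerated null p
  # distribution (tie-free data: p depends only on the rank split)
  ranks <- 1:11
  splits <- utils::combn(11, 5)
  null_p <- apply(splits, 2, function(idx) {
    oracle_mw_p(ranks[idx], ranks[-idx])
  })
  size_mw <- mean(null_p < 0.05)
  n_sim <- 2000
  set.seed(20260911)
  rej_mw <- 0L
  rej_welch <- 0L
  for (i in seq_len(n_sim)) {
    x <- rnorm(5)
    y <- rnorm(6)
    if (mann_whitney_u(x, y)$p_two_sided < 0.05) rej_mw <- rej_mw + 1L
    if (welch_t(x, y)$p_two_sided < 0.05) rej_welch <- rej_welch + 1L
  }
  ci_mw <- qbinom(c(0.005, 0.995), n_sim, size_mw)
  expect_gte(rej_mw, ci_mw[1])
  expect_lte(rej_mw, ci_mw[2])
  ci_welch <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(rej_welch, ci_welch[1])
  expect_lte(rej_welch, ci_welch[2])
})
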