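mk_matrix <- function(levels, groups) {
  n_ev <- nrow(levels)
  events <- data.frame(contig = "chr1", pos = seq_len(n_ev),
                       ref_allele = "G", alt_allele = "A",
                       stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = paste0("s", seq_along(groups)),
                      group = groups, stringsAsFactors = FALSE)
  new_editing_matrix(levels, events, sheet)
}

test_that("group comparison is a pooled-variance Student t with conventions", {
  g <- c("a", "a", "a", "b", "b", "b")
  # identical values in both groups: t = 0, p = 1
  m <- mk_matrix(matrix(0.2, 1, 6), g)
  r <- compare_groups(m, "a", "b")
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)
  expect_true(r$degenerate)
  # zero pooled variance with distinct means: p -> 0 convention
  m2 <- mk_matrix(matrix(c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5), 1), g)
  r2 <- compare_groups(m2, "a", "b")
  expect_identical(r2$p, 0)
  expect_true(r2$degenerate)
  expect_identical(r2$direction, "up")
  # agreement with the reference implementation on non-degenerate data
  set.seed(5)
  lv <- matrix(runif(60, 0.05, 0.9), 10, 6)
  m3 <- mk_matrix(lv, g)
  r3 <- compare_groups(m3, "a", "b")
  for (i in 1:10) {
    tt <- t.test(lv[i, 4:6], lv[i, 1:3], var.equal = TRUE)
    expect_equal(r3$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(r3$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  w3 <- compare_groups(m3, "a", "b", welch = TRUE)
  tt <- t.test(lv[1, 4:6], lv[1, 1:3])
  expect_equal(w3$p[1], tt$p.value, tolerance = 1e-12)
  # missing-data rule: below min_n the event is untestable
  lv4 <- matrix(c(0.1, NA, NA, 0.4, 0.5, 0.6), 1)
  r4 <- compare_groups(mk_matrix(lv4, g), "a", "b")
  expect_false(r4$testable)
  expect_true(is.na(r4$p))
  expect_error(compare_groups(m, "a", "zzz"), "group not in matrix")
})

test_that("t-test p is close to the exhaustive permutation distribution", {
  set.seed(31)
  x <- round(runif(4, 0.1, 0.4), 3)
  y <- round(runif(4, 0.3, 0.6), 3)
  m <- mk_matrix(matrix(c(x, y), 1), rep(c("a", "b"), each = 4))
  p_t <- compare_groups(m, "a", "b")$p
  vals <- c(x, y)
  tstat <- function(idx) {
    xs <- vals[idx]; ys <- vals[-idx]
    sp <- ((3) * var(xs) + (3) * var(ys)) / 6
    (mean(ys) - mean(xs)) / sqrt(sp * (1 / 4 + 1 / 4))
  }
  obs <- abs(tstat(1:4))
  perms <- combn(8, 4)
  t_all <- abs(apply(perms, 2, tstat))
  p_perm <- mean(t_all >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.1)
})

test_that("swapping group labels flips direction and preserves p", {
  set.seed(8)
  lv <- matrix(runif(30, 0, 1), 5, 6)
  g <- rep(c("a", "b"), each = 3)
  m <- mk_matrix(lv, g)
  r_ab <- compare_groups(m, "a", "b")
  r_ba <- compare_groups(m, "b", "a")
  expect_equal(r_ab$p, r_ba$p)
  expect_equal(r_ab$t, -r_ba$t)
  flip <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(flip[r_ab$direction]), r_ba$direction)
})

test_that("detection overlap conserves the union and its fractions", {
  o <- detection_overlap(c("x", "y", "z"), c("y", "z", "w"))
  expect_identical(c(o$shared, o$a_only, o$b_only), c(2L, 1L, 1L))
  expect_equal(o$frac_shared + o$frac_a_only + o$frac_b_only, 1)
  same <- detection_overlap(letters[1:4], letters[1:4])
  expect_identical(same$shared, 4L)
  expect_equal(c(same$frac_shared, same$frac_a_only), c(1, 0))
  expect_identical(detection_overlap(letters[1:3], letters[10:12])$shared, 0L)
  # permutation invariance
  o2 <- detection_overlap(c("z", "y", "x"), c("w", "z", "y"))
  expect_identical(o2$shared, o$shared)
})

test_that("PCA variance fractions match a covariance eigen-decomposition", {
  g <- rep(c("a", "b"), each = 3)
  # identical samples: degenerate
  expect_error(pca_events(mk_matrix(matrix(0.3, 4, 6), g)), "degenerate")
  # rank-1 structure: PC1 explains everything
  lv <- matrix(0.2, 3, 6); lv[1, ] <- c(0.1, 0.1, 0.1, 0.6, 0.6, 0.6)
  p1 <- pca_events(mk_matrix(lv, g))
  expect_equal(p1$var_explained[1], 1)
  # general case against eigenvalues of the sample covariance
  set.seed(21)
  lv2 <- matrix(runif(48), 8, 6)
  p2 <- pca_events(mk_matrix(lv2, g))
  ev <- eigen(cov(t(lv2)), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(p2$var_explained[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-8)
  expect_equal(sum(p2$var_explained), 1)
  # event-wise mean imputation keeps missing data usable
  lv3 <- lv2; lv3[1, 2] <- NA
  expect_silent(pca_events(mk_matrix(lv3, g)))
  expect_error(pca_events(mk_matrix(matrix(0.1, 2, 1),  "a")), "2 samples")
})

test_that("Spearman correlation uses average ranks and handles ties", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(spearman_correlation(x, x), 1)
  expect_equal(spearman_correlation(x, rev(x)), -1)
  # hand-ranked oracle with ties: ranks via the average-rank definition
  xt <- c(1, 2, 2, 3); yt <- c(10, 20, 25, 20)
  rho_hand <- cor(rank(xt), rank(yt))
  expect_equal(spearman_correlation(xt, yt), rho_hand)
  expect_true(is.na(spearman_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Fisher two-sided p matches enumeration and the reference test", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 1, 1, 1)), 1)
  t2 <- contingency_2x2(10, 0, 0, 10)
  expect_equal(fisher_exact_two_sided(t2), fisher_oracle(10, 0, 0, 10),
               tolerance = 1e-12)
  # the published enrichment tables, against enumeration to 1e-10 relative
  for (cells in list(c(1739, 752, 29, 33), c(1731, 744, 37, 41))) {
    p <- fisher_exact_two_sided(do.call(contingency_2x2, as.list(cells)))
    po <- do.call(fisher_oracle, as.list(cells))
    expect_lt(abs(p - po) / po, 1e-10)
    pr <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, pr, tolerance = 1e-6)
  }
  set.seed(3)
  for (i in 1:20) {
    cells <- as.list(sample(0:25, 4, replace = TRUE))
    if (do.call(sum, cells) == 0) next
    p <- fisher_exact_two_sided(do.call(contingency_2x2, cells))
    expect_equal(p, do.call(fisher_oracle, cells), tolerance = 1e-12)
  }
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("odds ratio and Woolf interval behave as published", {
  o1 <- odds_ratio_with_ci(contingency_2x2(1739, 752, 29, 33))
  expect_equal(round(o1$or, 1), 2.6)
  o2 <- odds_ratio_with_ci(contingency_2x2(1731, 744, 37, 41))
  expect_equal(round(o2$or, 1), 2.6)
  expect_true(o1$lower < o1$or && o1$or < o1$upper)
  # symmetric table: OR = 1
  expect_equal(odds_ratio_with_ci(contingency_2x2(5, 5, 5, 5))$or, 1)
  # swapping the rows inverts the OR
  a <- odds_ratio_with_ci(contingency_2x2(12, 5, 7, 9))
  b <- odds_ratio_with_ci(contingency_2x2(7, 9, 12, 5))
  expect_equal(a$or, 1 / b$or)
  # zero cell: Haldane-Anscombe correction, flagged
  z <- odds_ratio_with_ci(contingency_2x2(10, 0, 3, 5))
  expect_true(z$haldane)
  expect_true(is.finite(z$or))
})

test_that("multi-event enrichment builds the 2x2 with fixed semantics", {
  counts <- c(X = 1, Y = 3, Z = 1, W = 2)
  e <- multi_event_enrichment(counts, diff_genes = c("X", "Y"))
  expect_equal(unlist(e$table[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  # degenerate: no differential genes
  e0 <- multi_event_enrichment(counts, diff_genes = character(0))
  expect_equal(e0$table$c + e0$table$d, 0)
  expect_true(e0$haldane)
  expect_error(multi_event_enrichment(numeric(0), "X"), "empty")
  expect_error(multi_event_enrichment(counts, "nope"), "absent")
  # accepts the per-gene aggregation data.frame directly
  df <- data.frame(gene_id = names(counts), n_events = unname(counts))
  expect_identical(multi_event_enrichment(df, c("X", "Y"))$table,
                   e$table)
})

test_that("planted count-dependent differential odds are recovered", {
  set.seed(97)
  n_single <- 1768; n_multi <- 785   # gene universe of the published scale
  or_true <- 2.6
  p1 <- 0.03
  odds2 <- p1 / (1 - p1) * or_true
  p2 <- odds2 / (1 + odds2)
  counts <- c(rep(1, n_single), rep(2, n_multi))
  names(counts) <- sprintf("g%04d", seq_along(counts))
  diff <- c(runif(n_single) < p1, runif(n_multi) < p2)
  e <- multi_event_enrichment(counts, names(counts)[diff])
  expect_true(e$lower <= or_true && or_true <= e$upper)
})

test_that("TPM normalizes by length and sums to one million", {
  expect_equal(unname(tpm_from_counts(c(g = 50), c(g = 1000))), 1e6)
  t2 <- tpm_from_counts(c(a = 100, b = 100), c(a = 1000, b = 2000))
  expect_equal(unname(t2["a"] / t2["b"]), 2)
  set.seed(2)
  cn <- rpois(50, 200); names(cn) <- paste0("g", 1:50)
  ln <- sample(500:5000, 50); names(ln) <- names(cn)
  expect_equal(sum(tpm_from_counts(cn, ln)), 1e6, tolerance = 1e-6)
  expect_warning(z <- tpm_from_counts(c(a = 0, b = 0), c(a = 10, b = 10)),
                 "zero")
  expect_identical(unname(z), c(0, 0))
  expect_error(tpm_from_counts(c(a = 1), c(a = 0)), "positive")
})

test_that("expression comparison works on log-TPM with adequate power", {
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      group = rep(c("a", "b"), each = 3))
  tpm <- matrix(100, 3, 6, dimnames = list(paste0("g", 1:3), sheet$sample_id))
  r <- compare_expression(tpm, sheet, "a", "b")
  expect_true(all(r$p == 1))
  # two-fold change, 10% CV, n = 3/group: detected in >= 90% of draws
  set.seed(55)
  hits <- 0
  for (i in 1:100) {
    g1 <- rnorm(3, 100, 10); g2 <- rnorm(3, 200, 20)
    m <- matrix(c(g1, g2), 1, 6, dimnames = list("g1", sheet$sample_id))
    res <- compare_expression(m, sheet, "a", "b")
    if (isTRUE(res$significant)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
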