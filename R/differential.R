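two_group_ttest <- function(values, groups, g1, g2, alpha = 0.05,
                            min_n = 2L, welch = FALSE, fdr = FALSE) {
  if (!g1 %in% groups) stop("group not in matrix: ", g1)
  if (!g2 %in% groups) stop("group not in matrix: ", g2)
  i1 <- which(groups == g1)
  i2 <- which(groups == g2)
  one <- function(row) {
    x <- row[i1]; y <- row[i2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    out <- list(mean_g1 = NA_real_, mean_g2 = NA_real_, n_g1 = n1,
                n_g2 = n2, t = NA_real_, df = NA_real_, p = NA_real_,
                direction = NA_character_, degenerate = FALSE,
                testable = FALSE)
    if (n1 < min_n || n2 < min_n) return(out)
    m1 <- mean(x); m2 <- mean(y)
    out$mean_g1 <- m1; out$mean_g2 <- m2; out$testable <- TRUE
    out$direction <- if (m2 > m1) "up" else if (m2 < m1) "down" else "none"
    v1 <- stats::var(x); v2 <- stats::var(y)
    if (welch) {
      se2 <- v1 / n1 + v2 / n2
      if (se2 == 0) {
        out$degenerate <- TRUE
        out$p <- if (m1 == m2) 1 else 0
        out$t <- if (m1 == m2) 0 else Inf * sign(m2 - m1)
        return(out)
      }
      out$t <- (m2 - m1) / sqrt(se2)
      out$df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      if (s2p == 0) {
        out$degenerate <- TRUE
        out$p <- if (m1 == m2) 1 else 0
        out$t <- if (m1 == m2) 0 else Inf * sign(m2 - m1)
        return(out)
      }
      out$t <- (m2 - m1) / sqrt(s2p * (1 / n1 + 1 / n2))
      out$df <- n1 + n2 - 2
    }
    out$p <- 2 * stats::pt(-abs(out$t), out$df)
    out
  }
  res <- lapply(seq_len(nrow(values)),
                function(i) one(values[i, , drop = TRUE]))
  if (length(res) == 0L) {
    tab <- data.frame(mean_g1 = numeric(0), mean_g2 = numeric(0),
                      n_g1 = integer(0), n_g2 = integer(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      direction = character(0), degenerate = logical(0),
                      testable = logical(0), stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, lapply(res, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
  }
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- if (fdr) !is.na(tab$p_adj) & tab$p_adj < alpha
    else !is.na(tab$p) & tab$p < alpha
  tab
}

#' Differential editing between two groups
#'
#' Classic two-sample Student's t-test (pooled variance) on each event's
#' editing levels, two-sided, significance at p < `alpha` without
#' multiple-testing correction by default (an optional Benjamini-Hochberg
#' mode is available via `fdr = TRUE`, and Welch's test via
#' `welch = TRUE`). Events with fewer than `min_n` non-missing values in
#' either group are reported as untestable. When the pooled variance is
#' exactly zero the test degenerates: p = 1 for equal means, p = 0
#' otherwise, flagged in the `degenerate` column.
#'
#' @param mat An `EditingMatrix`.
#' @param g1,g2 Group labels; direction is reported for `g2` relative to
#'   `g1`.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum non-missing values per group per event.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @param fdr Call significance on BH-adjusted p-values instead of raw.
#' @return data.frame with event keys, group means/sizes, t, df, p,
#'   p_adj, direction ("up"/"down" in g2 vs g1), degenerate, testable,
#'   significant.
#' @export
compare_groups <- function(mat, g1, g2, alpha = 0.05, min_n = 2L,
                           welch = FALSE, fdr = FALSE) {
  tab <- two_group_ttest(mat$levels, mat$samples$group, g1, g2,
                         alpha = alpha, min_n = min_n, welch = welch,
                         fdr = fdr)
  cbind(mat$events[, c("contig", "pos", "ref_allele", "alt_allele")],
        tab)
}

#' Detection overlap between two event sets
#'
#' @param setA,setB Character vectors of event keys.
#' @return list(shared, a_only, b_only, union, frac_shared, frac_a_only,
#'   frac_b_only); the three fractions are of the union and sum to 1.
#' @export
detection_overlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- length(intersect(setA, setB))
  a_only <- length(setdiff(setA, setB))
  b_only <- length(setdiff(setB, setA))
  u <- shared + a_only + b_only
  list(shared = shared, a_only = a_only, b_only = b_only, union = u,
       frac_shared = if (u > 0) shared / u else NA_real_,
       frac_a_only = if (u > 0) a_only / u else NA_real_,
       frac_b_only = if (u > 0) b_only / u else NA_real_)
}

#' Principal component analysis of editing levels
#'
#' Samples are observations, events variables. Missing levels are imputed
#' with the event-wise mean; the decomposition is centered but not scaled.
#'
#' @param mat An `EditingMatrix` (typically restricted to differential
#'   events).
#' @return list(scores = samples x components matrix, var_explained =
#'   fractions of total variance summing to 1, rotation).
#' @export
pca_events <- function(mat) {
  lv <- mat$levels
  if (ncol(lv) < 2L) stop("fewer than 2 samples")
  all_na <- apply(lv, 1L, function(r) all(is.na(r)))
  if (any(all_na)) {
    warning(sum(all_na), " event(s) with no measured level dropped")
    lv <- lv[!all_na, , drop = FALSE]
  }
  if (nrow(lv) == 0L) stop("no events with measured levels")
  for (i in seq_len(nrow(lv))) {
    miss <- is.na(lv[i, ])
    if (any(miss)) lv[i, miss] <- mean(lv[i, ], na.rm = TRUE)
  }
  x <- t(lv)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  if (tot <= 0) stop("degenerate: samples are identical, no variance")
  list(scores = pr$x, var_explained = pr$sdev^2 / tot,
       rotation = pr$rotation)
}

#' Spearman rank correlation
#'
#' Average ranks are used for ties. A constant vector has no defined rank
#' correlation and yields `NA`.
#'
#' @param x,y Equal-length numeric vectors (pairwise-complete; pairs with
#'   any `NA` are dropped). At least 3 complete pairs required.
#' @return rho in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' 2x2 contingency table for multi-event-gene enrichment
#'
#' Fixed semantics: rows are gene NOT differential (a, b) / differential
#' (c, d); columns are event count = 1 (a, c) / event count > 1 (b, d).
#'
#' @param a,b,c,d Non-negative integer cells.
#' @return A list of class `ContingencyTable2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all cells must be non-negative")
  structure(as.list(cells), class = "ContingencyTable2x2")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability
#' of the observed table (with a 1e-7 relative tolerance for
#' floating-point ties, the conventional rule).
#'
#' @param tab A `ContingencyTable2x2` from [contingency_2x2()].
#' @return p-value in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(tab) {
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0L, k - n):min(k, m)
  pmf <- stats::dhyper(supp, m, n, k)
  p_obs <- pmf[supp == a]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Sample odds ratio with a Woolf log-interval
#'
#' OR = (a d)/(b c); the confidence interval is
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). A zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to every cell), flagged in the
#' result.
#'
#' @param tab A `ContingencyTable2x2`.
#' @param level Confidence level (default 0.95).
#' @return list(or, lower, upper, level, haldane).
#' @export
odds_ratio_with_ci <- function(tab, level = 0.95) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lower = exp(log(or) - z * se),
       upper = exp(log(or) + z * se), level = level, haldane = haldane)
}

#' Enrichment of differential editing in multi-event genes
#'
#' Builds the 2x2 table — gene differential or not, against single-event
#' versus multi-event — and tests association with Fisher's exact test
#' plus the sample odds ratio.
#'
#' @param gene_counts Named integer vector (or data.frame gene_id /
#'   n_events as from [aggregate_per_gene()]): events per gene.
#' @param diff_genes Character vector of genes carrying at least one
#'   significantly differential event; must be a subset of the genes in
#'   `gene_counts`.
#' @param level Confidence level for the odds-ratio interval.
#' @return list(table = `ContingencyTable2x2`, p, or, lower, upper,
#'   haldane).
#' @export
multi_event_enrichment <- function(gene_counts, diff_genes = character(0),
                                   level = 0.95) {
  if (is.data.frame(gene_counts)) {
    counts <- gene_counts$n_events
    names(counts) <- gene_counts$gene_id
    gene_counts <- counts
  }
  if (length(gene_counts) == 0L) stop("empty gene counts")
  extra <- setdiff(diff_genes, names(gene_counts))
  if (length(extra) > 0L)
    stop("differential gene(s) absent from counts: ",
         paste(extra, collapse = ", "))
  multi <- gene_counts > 1L
  diff <- names(gene_counts) %in% diff_genes
  tab <- contingency_2x2(a = sum(!diff & !multi), b = sum(!diff & multi),
                         c = sum(diff & !multi), d = sum(diff & multi))
  orci <- odds_ratio_with_ci(tab, level = level)
  c(list(table = tab, p = fisher_exact_two_sided(tab)), orci)
}

#' TPM from gene counts and lengths
#'
#' rate_g = counts_g / length_g(kb); TPM_g = 1e6 * rate_g / sum(rates).
#' TPMs sum to 1e6 whenever any count is positive.
#'
#' @param counts Named non-negative numeric vector of read counts.
#' @param lengths Named positive numeric vector of gene lengths in nt,
#'   same genes as `counts`.
#' @return Named numeric vector of TPMs.
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (!is.null(names(counts)) && !is.null(names(lengths)))
    lengths <- lengths[names(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and cover all counted genes")
  rate <- counts / (lengths / 1000)
  s <- sum(rate)
  if (s == 0) {
    warning("all counts are zero; TPMs are all zero")
    return(rate)
  }
  1e6 * rate / s
}

#' Differential gene expression between two groups
#'
#' The same t-test machinery as [compare_groups()], applied to
#' log2(TPM + 1)-transformed expression.
#'
#' @param tpm Genes x samples matrix of TPM values.
#' @param sample_sheet data.frame(sample_id, group) in column order of
#'   `tpm`.
#' @inheritParams compare_groups
#' @return data.frame with gene_id plus the t-test columns.
#' @export
compare_expression <- function(tpm, sample_sheet, g1, g2, alpha = 0.05,
                               min_n = 2L, welch = FALSE, fdr = FALSE) {
  stopifnot(ncol(tpm) == nrow(sample_sheet))
  tab <- two_group_ttest(log2(tpm + 1), sample_sheet$group, g1, g2,
                         alpha = alpha, min_n = min_n, welch = welch,
                         fdr = fdr)
  cbind(data.frame(gene_id = rownames(tpm), stringsAsFactors = FALSE),
        tab)
}
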