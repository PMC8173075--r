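test_that("edit type is reported in transcript orientation", {
  expect_identical(classify_edit_type("G", "A", "+"), "G-to-A")
  expect_identical(classify_edit_type("C", "T", "-"), "G-to-A")
  expect_identical(classify_edit_type("G", "A", "-"), "C-to-T")
  expect_identical(classify_edit_type("A", "G", "+"), "A-to-G")
  expect_error(classify_edit_type("G", "A", "."), "gene_strand")
})

test_that("germline AAF pattern filter counts the het band and homozygotes", {
  cfg <- cascade_config()
  expect_true(germline_pattern_filter(rep(0.5, 6), cfg))
  expect_false(germline_pattern_filter(rep(0.15, 6), cfg))
  # 5/6 ~ 0.833 is not > 0.9
  expect_false(germline_pattern_filter(c(rep(1, 5), 0.1), cfg))
  # band endpoints are inclusive, 1.00 counts
  expect_true(germline_pattern_filter(c(0.40, 0.60, 1, 1, 1, 1), cfg))
  # just outside the band does not count
  expect_false(germline_pattern_filter(c(0.39, 0.61, 1, 1, 0.2, 0.2), cfg))
  # uncovered samples leave the denominator under the default mode
  expect_true(germline_pattern_filter(c(0.5, 0.5, NA, NA, NA, NA), cfg))
  cfg_all <- cascade_config(germline_denominator = "all")
  expect_false(germline_pattern_filter(c(0.5, 0.5, NA, NA, NA, NA), cfg_all))
  # no callable sample: cannot evaluate, keep
  expect_false(germline_pattern_filter(rep(NA_real_, 6), cfg))
})

test_that("site filters flag independently and rescue voids all flags", {
  b <- make_test_bundle()
  cfg <- cascade_config()
  lv <- c(0.2, 0.25, 0.1)
  flags_at <- function(contig, pos, ref = "G", alt = "A",
                       indels = integer(0)) {
    apply_site_filters(list(contig = contig, pos = pos, ref_allele = ref,
                            alt_allele = alt, levels = lv),
                       b, indel_positions = indels, cfg = cfg)
  }
  # mitochondrial contig
  f <- flags_at("chrM", 50)
  expect_true(f$filter_flags[["mitochondrial"]])
  expect_false(f$clean)
  # splice distance 6 flagged, 7 kept (junction at 201)
  expect_true(flags_at("chr1", 195)$filter_flags[["near_splice"]])
  f7 <- flags_at("chr1", 194)
  expect_false(f7$filter_flags[["near_splice"]])
  expect_true(f7$clean)
  # homopolymer run 5 abutting flagged; run 4 kept
  expect_true(flags_at("chr1", 246)$filter_flags[["repeat_or_homopolymer"]])
  expect_false(flags_at("chr1", 265)$filter_flags[["repeat_or_homopolymer"]])
  # repeat mask
  expect_true(flags_at("chr1", 610)$filter_flags[["repeat_or_homopolymer"]])
  # dbSNP with matching alleles flags; other alleles at the position do not
  expect_true(flags_at("chr1", 259)$filter_flags[["dbsnp_known"]])
  expect_true(flags_at("chr1", 271)$clean)  # catalogued allele is A>C
  # INDEL within 1 nt flags; 2 nt away does not
  expect_true(flags_at("chr1", 55, indels = 56L)$filter_flags[["near_indel"]])
  expect_false(flags_at("chr1", 55, indels = 57L)$filter_flags[["near_indel"]])
  # germline pattern
  g <- apply_site_filters(list(contig = "chr1", pos = 55, ref_allele = "G",
                               alt_allele = "A", levels = rep(0.5, 6)),
                          b, cfg = cfg)
  expect_true(g$filter_flags[["germline_pattern"]])
  # known-editing rescue: site 246 is homopolymer-flagged AND catalogued
  r <- flags_at("chr1", 246)
  expect_true(r$rescued)
  expect_true(r$clean)
  # rescue also voids multiple simultaneous flags (site 207: near splice)
  r2 <- flags_at("chr1", 207)
  expect_true(r2$filter_flags[["near_splice"]])
  expect_true(r2$clean)
})

test_that("AAF-band filter separates het SNPs from editing at deep coverage", {
  cfg <- cascade_config()
  set.seed(61)
  depth <- 300L; n_samples <- 9L
  het_removed <- replicate(200, {
    lv <- stats::rbinom(n_samples, depth, 0.5) / depth
    germline_pattern_filter(lv, cfg)
  })
  expect_gte(mean(het_removed), 0.95)
  edit_removed <- replicate(200, {
    lv <- stats::rbinom(n_samples, depth, 0.25) / depth
    germline_pattern_filter(lv, cfg)
  })
  expect_lte(mean(edit_removed), 0.05)
})

micro_study <- function(known_pos = c(207, 246)) {
  b <- make_test_bundle(known_pos = known_pos)
  # clean genic G-to-A sites: X=55, Z=59 (geneA +), W=394 (geneB -, C ref)
  # Y=235 (geneA +) is the replication-route site
  d1 <- write_pileup(c(
    mk_pileup_line("chr1", 55, "G", 7, 7, "A", 2, 2),
    mk_pileup_line("chr1", 59, "G", 8, 8, "A", 2, 2),
    mk_pileup_line("chr1", 235, "G", 9, 9, "A", 3, 3),
    mk_pileup_line("chr1", 394, "C", 7, 7, "T", 2, 2)))
  d2 <- write_pileup(c(
    mk_pileup_line("chr1", 55, "G", 8, 8, "A", 3, 3),
    mk_pileup_line("chr1", 59, "G", 10, 10),
    mk_pileup_line("chr1", 235, "G", 10, 10),
    mk_pileup_line("chr1", 394, "C", 8, 8, "T", 3, 3)))
  d3 <- write_pileup(c(
    mk_pileup_line("chr1", 55, "G", 10, 10),
    mk_pileup_line("chr1", 59, "G", 10, 10),
    mk_pileup_line("chr1", 235, "G", 10, 10),
    mk_pileup_line("chr1", 394, "C", 10, 10)))
  c1 <- write_pileup(c(
    mk_pileup_line("chr1", 55, "G", 10, 10),
    mk_pileup_line("chr1", 59, "G", 10, 10),
    mk_pileup_line("chr1", 235, "G", 19, 19, "A", 1, 1),
    mk_pileup_line("chr1", 394, "C", 10, 10)))
  discovery <- list(call_sample(d1, sample_id = "d1"),
                    call_sample(d2, sample_id = "d2"),
                    call_sample(d3, sample_id = "d3"))
  cohort <- list(call_sample(c1, sample_id = "c1"))
  list(bundle = b, discovery = discovery, cohort = cohort)
}

test_that("admission requires the multi-sample / replication disjunction", {
  ms <- micro_study()
  hcs <- build_high_confidence_set(ms$discovery, ms$cohort, ms$bundle)
  ev <- hcs$events
  expect_setequal(ev$pos, c(55L, 235L, 394L))
  expect_identical(ev$provenance[ev$pos == 55], "multi_sample")
  expect_identical(ev$provenance[ev$pos == 394], "multi_sample")
  expect_identical(ev$provenance[ev$pos == 235], "replication")
  # Z (59) was called once and never replicated
  cand <- hcs$candidates
  expect_false(cand$admitted[cand$pos == 59])
  expect_identical(cand$n_discovery[cand$pos == 59], 1L)
  # minus-strand site is a transcript G-to-A
  expect_identical(ev$edit_type[ev$pos == 394], "G-to-A")
  expect_identical(ev$gene_id[ev$pos == 394], "geneB")
  # levels matrix holds editing levels with explicit missingness rules
  expect_equal(unname(hcs$levels["chr1:55:G:A", "d1"]), 4 / 18)
  expect_equal(unname(hcs$levels["chr1:55:G:A", "d3"]), 0)
  # no event is invented: admitted set within the pooled call positions
  pooled <- unlist(lapply(ms$discovery, function(s) s$calls$pos))
  cohort_pos <- unlist(lapply(ms$cohort, function(s) s$calls$pos))
  expect_true(all(ev$pos %in% c(pooled, cohort_pos)))
  expect_error(build_high_confidence_set(list(), ms$cohort, ms$bundle),
               "no samples")
})

test_that("adding a site to the known-editing catalogue never removes events", {
  ms0 <- micro_study(known_pos = 1)        # effectively empty catalogue
  ms1 <- micro_study(known_pos = c(55, 235, 394))
  h0 <- build_high_confidence_set(ms0$discovery, ms0$cohort, ms0$bundle)
  h1 <- build_high_confidence_set(ms1$discovery, ms1$cohort, ms1$bundle)
  k0 <- paste(h0$events$contig, h0$events$pos)
  k1 <- paste(h1$events$contig, h1$events$pos)
  expect_true(all(k0 %in% k1))
  # and removing it never admits others
  expect_setequal(setdiff(k1, k0), character(0))
})

test_that("per-gene aggregation partitions the admitted events", {
  hcs <- structure(list(events = data.frame(
    gene_id = c("X", "X", "X", "Y"), stringsAsFactors = FALSE)),
    class = "HighConfidenceSet")
  tab <- aggregate_per_gene(hcs)
  expect_identical(tab$gene_id, c("X", "Y"))
  expect_identical(tab$n_events, c(3L, 1L))
  expect_identical(sum(tab$n_events), 4L)
  empty <- structure(list(events = data.frame(gene_id = character(0))),
                     class = "HighConfidenceSet")
  expect_identical(nrow(aggregate_per_gene(empty)), 0L)
})

test_that("editing matrix restricts to admitted events with group labels", {
  ms <- micro_study()
  hcs <- build_high_confidence_set(ms$discovery, ms$cohort, ms$bundle)
  sheet <- data.frame(sample_id = c("d1", "d2", "d3"),
                      group = c("a", "a", "b"), stringsAsFactors = FALSE)
  mat <- editing_matrix(hcs, sheet)
  expect_identical(dim(mat$levels), c(3L, 3L))
  expect_true(all(mat$levels[!is.na(mat$levels)] >= 0 &
                    mat$levels[!is.na(mat$levels)] <= 1))
  expect_error(editing_matrix(hcs, data.frame(sample_id = "zz",
                                              group = "a")),
               "absent")
})
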