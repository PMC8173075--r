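# Fixtures are built in code at test time; nothing binary is stored.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# chr1 is a repeating ACGT pattern (no homopolymer runs: G at pos %% 4 == 3,
# C at pos %% 4 == 2), with explicit per-position overrides.
pattern_seq <- function(len, overrides = list()) {
  v <- rep(c("A", "C", "G", "T"), length.out = len)
  for (p in names(overrides)) v[as.integer(p)] <- overrides[[p]]
  paste(v, collapse = "")
}

gtf_line <- function(contig, type, start, end, strand, gid, gname) {
  paste(contig, "test", type, start, end, ".", strand, if (type == "CDS") "0" else ".",
        sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
                gid, gname),
        sep = "\t")
}

# two-gene annotation used across the filter tests:
#   geneA "+" exons [11,100],[201,300], CDS [31,100]+[201,262] (132 nt)
#   geneB "-" exons [351,420],[481,560], CDS [370,420]+[481,540] (111 nt)
# junctions: 100, 201, 420, 481
write_test_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    gtf_line("chr1", "gene", 11, 300, "+", "geneA", "GnA"),
    gtf_line("chr1", "exon", 11, 100, "+", "geneA", "GnA"),
    gtf_line("chr1", "exon", 201, 300, "+", "geneA", "GnA"),
    gtf_line("chr1", "CDS", 31, 100, "+", "geneA", "GnA"),
    gtf_line("chr1", "CDS", 201, 262, "+", "geneA", "GnA"),
    gtf_line("chr1", "gene", 351, 560, "-", "geneB", "GnB"),
    gtf_line("chr1", "exon", 351, 420, "-", "geneB", "GnB"),
    gtf_line("chr1", "exon", 481, 560, "-", "geneB", "GnB"),
    gtf_line("chr1", "CDS", 370, 420, "-", "geneB", "GnB"),
    gtf_line("chr1", "CDS", 481, 540, "-", "geneB", "GnB")), path)
  path
}

write_sites_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>", "##contig=<ID=chrM>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

write_known_tsv <- function(pos, path = tempfile(fileext = ".tsv"),
                            contig = "chr1") {
  df <- data.frame(contig = rep(contig, length(pos)), pos = pos,
                   strand = "+", type = "G-to-A")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# bundle with homopolymer run-5 at 241:245 (site 246 abuts it), run-4 at
# 261:264 (site 265 abuts it), a repeat interval [601,620], dbSNP G>A at
# 259 and A>C at 271, known-editing at 207 and 246
make_test_bundle <- function(known_pos = c(207, 246)) {
  fa <- write_fasta(list(
    chr1 = pattern_seq(640, list(`241` = "A", `242` = "A", `243` = "A",
                                 `244` = "A", `245` = "A",
                                 `261` = "C", `262` = "C", `263` = "C",
                                 `264` = "C")),
    chrM = pattern_seq(100)))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t600\t620", bed)  # BED half-open -> 1-based [601,620]
  vcf <- write_sites_vcf(c("chr1\t259\t.\tG\tA\t.\tPASS\t.",
                           "chr1\t271\t.\tA\tC\t.\tPASS\t."))
  reference_bundle(fa, write_test_gtf(), bed, vcf,
                   write_known_tsv(known_pos))
}

# pileup line with explicit ref/alt strand counts, one quality for all
mk_pileup_line <- function(contig, pos, ref, nref_f = 5, nref_r = 5,
                           alt = NULL, nalt_f = 0, nalt_r = 0,
                           qual = "I") {
  bases <- paste0(strrep(".", nref_f), strrep(",", nref_r),
                  if (!is.null(alt)) paste0(strrep(alt, nalt_f),
                                            strrep(tolower(alt), nalt_r)))
  depth <- nref_f + nref_r + nalt_f + nalt_r
  paste(contig, pos, ref, depth, bases, strrep(qual, depth), sep = "\t")
}

write_pileup <- function(lines, path = tempfile(fileext = ".pileup")) {
  writeLines(lines, path)
  path
}

summary_from_line <- function(line, q_min = 25L) {
  summarize_site(parse_pileup_line(line), q_min = q_min)
}

# hand-built variant-call row for false_positive_filter tests
mk_call <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                    mean_q_alt = 35, mean_q_ref = 35) {
  data.frame(sample_id = "s", contig = "chr1", pos = 100L,
             ref_allele = "G", alt_allele = "A", kind = "SNV",
             total_depth = alt_fwd + alt_rev + ref_fwd + ref_rev,
             alt_depth = alt_fwd + alt_rev,
             aaf = (alt_fwd + alt_rev) /
               (alt_fwd + alt_rev + ref_fwd + ref_rev),
             alt_fwd = alt_fwd, alt_rev = alt_rev,
             ref_fwd = ref_fwd, ref_rev = ref_rev,
             mean_q_alt = mean_q_alt, mean_q_ref = mean_q_ref,
             stringsAsFactors = FALSE)
}

# reduced synthetic study for fast integration tests
small_sim_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 10L, n_reference = 3L,
               n_edit_sites = 20L, n_diff_sites = 6L,
               n_germline_het = 6L, n_germline_hom = 4L,
               n_artifact_homopolymer = 3L,
               n_artifact_near_junction = 3L,
               n_artifact_strand_bias = 3L, n_mito_sites = 2L,
               n_background = 40L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

truth_from_dir <- function(dir) {
  structure(list(
    edits = read.delim(file.path(dir, "truth_edits.tsv")),
    snps = read.delim(file.path(dir, "truth_snps.tsv")),
    artifacts = read.delim(file.path(dir, "truth_artifacts.tsv")),
    background = data.frame()), class = "GroundTruth")
}

# independent hypergeometric enumeration (log-binomial arithmetic only)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  pmf <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k))
  min(1, sum(pmf[pmf <= pmf[supp == a] * (1 + 1e-7)]))
}
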