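#' Configuration of the synthetic editing study
#'
#' Defines the study the generator emulates: a 3/3/3 discovery design
#' (control, emotional-stress and physical-stress groups) plus an
#' independent reference cohort, negative-binomial site depths, binomial
#' sampling of edited reads, uniform base-call errors, and planted
#' editing sites, germline SNPs and alignment-artifact sites.
#'
#' @param seed Integer RNG seed; the same config and seed produce
#'   byte-identical output files.
#' @param n_control,n_es,n_ps Discovery samples per group.
#' @param n_reference Reference-cohort samples.
#' @param n_genes Genes on the main contig.
#' @param depth_mean,depth_size Negative-binomial site depth (mean, size).
#' @param error_rate Per-base error probability (uniform over the three
#'   other bases).
#' @param qual_mean,qual_sd Base qualities ~ Normal, clipped to \[2, 40\].
#' @param n_edit_sites Editing sites with equal levels in all groups.
#' @param edit_levels Levels cycled over the non-differential sites.
#' @param n_diff_sites Differential editing sites.
#' @param diff_levels Named vector of true levels (control, es, ps) at
#'   differential sites; the default is a 0.10 vs 0.30 shift.
#' @param n_germline_het,n_germline_hom Heterozygous (AAF 0.5 in every
#'   sample) and homozygous (AAF 1.0) germline SNPs.
#' @param fraction_dbsnp Fraction of planted SNPs listed in the synthetic
#'   dbSNP VCF.
#' @param n_artifact_homopolymer Sites planted beside a >= 5 nt run.
#' @param n_artifact_near_junction Sites planted within 6 nt of a splice
#'   junction.
#' @param n_artifact_strand_bias Sites whose alternate reads are emitted
#'   on one strand only.
#' @param n_mito_sites Variant sites on the mitochondrial contig.
#' @param artifact_level Alternate-read fraction at artifact sites.
#' @param n_background Covered positions with no planted variant.
#' @param fraction_known Fraction of planted editing sites listed in the
#'   known-editing catalogue.
#' @param edit_near_junction_frac Fraction of the non-differential editing
#'   sites deliberately placed within 6 nt of a junction (they are lost to
#'   the splice filter unless catalogued, which exercises rescue).
#' @param read_mark_rate Per-read probability of carrying a read-start
#'   (`^`) or read-end (`$`) mark in the emitted pileup.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_control = 3L, n_es = 3L, n_ps = 3L,
                              n_reference = 8L,
                              n_genes = 30L,
                              depth_mean = 50, depth_size = 10,
                              error_rate = 0.001,
                              qual_mean = 35, qual_sd = 4,
                              n_edit_sites = 150L,
                              edit_levels = c(0.05, 0.10, 0.15, 0.20,
                                              0.25, 0.30),
                              n_diff_sites = 40L,
                              diff_levels = c(control = 0.10, es = 0.30,
                                              ps = 0.30),
                              n_germline_het = 30L, n_germline_hom = 15L,
                              fraction_dbsnp = 1.0,
                              n_artifact_homopolymer = 10L,
                              n_artifact_near_junction = 10L,
                              n_artifact_strand_bias = 10L,
                              n_mito_sites = 3L,
                              artifact_level = 0.30,
                              n_background = 300L,
                              fraction_known = 0.30,
                              edit_near_junction_frac = 0,
                              read_mark_rate = 0.02) {
  stopifnot(seed == round(seed), abs(seed) < 2^31 - 2,
            n_control >= 0, n_es >= 0, n_ps >= 0, n_reference >= 0,
            n_genes >= 2, depth_mean > 0, depth_size > 0,
            error_rate >= 0, error_rate < 1,
            all(edit_levels >= 0), all(edit_levels <= 1),
            all(diff_levels >= 0), all(diff_levels <= 1),
            all(names(diff_levels) == c("control", "es", "ps")),
            fraction_dbsnp >= 0, fraction_dbsnp <= 1,
            fraction_known >= 0, fraction_known <= 1,
            edit_near_junction_frac >= 0, edit_near_junction_frac <= 1,
            artifact_level >= 0, artifact_level <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

sample_int <- function(lo, hi, n = 1L) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

# map a spliced (transcript-order-agnostic, genomic left-to-right)
# interval onto genomic intervals through the exon chain
spliced_to_genomic <- function(exons, s1, s2) {
  out <- NULL
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    len <- exons[i, "end"] - exons[i, "start"] + 1L
    lo <- max(s1, off + 1L)
    hi <- min(s2, off + len)
    if (lo <= hi) {
      es <- unname(exons[i, "start"])
      out <- rbind(out, c(start = es + (lo - off - 1L),
                          end = es + (hi - off - 1L)))
    }
    off <- off + len
  }
  out
}

break_runs_at <- function(seqvec, pos, max_run = 4L, protect = integer(0)) {
  # mutate bases near pos until no homopolymer run > max_run contains or
  # abuts pos; never touches pos itself or protected positions
  repeat {
    lo <- max(1L, pos - max_run - 2L)
    hi <- min(length(seqvec), pos + max_run + 2L)
    r <- rle(seqvec[lo:hi])
    ends <- cumsum(r$lengths) + lo - 1L
    starts <- ends - r$lengths + 1L
    bad <- which(r$lengths > max_run &
                   starts <= pos + 1L & ends >= pos - 1L)
    if (length(bad) == 0L) return(seqvec)
    i <- bad[1]
    cand <- setdiff(seq.int(starts[i], ends[i]), c(pos, protect))
    if (length(cand) == 0L) return(seqvec)
    t <- cand[length(cand)]
    repl <- setdiff(c("A", "C", "G", "T"), seqvec[max(1L, t - 1L):
                                                    min(length(seqvec), t + 1L)])
    seqvec[t] <- repl[1]
  }
}

write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    attr0 <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     g$gene_id, g$gene_name, g$biotype)
    span <- c(min(g$exons[, "start"]), max(g$exons[, "end"]))
    lines <- c(lines, paste("chr1", "synthetic", "gene", span[1], span[2],
                            ".", g$strand, ".", attr0, sep = "\t"))
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, paste("chr1", "synthetic", "exon",
                              g$exons[i, "start"], g$exons[i, "end"], ".",
                              g$strand, ".", attr0, sep = "\t"))
    for (i in seq_len(nrow(g$cds)))
      lines <- c(lines, paste("chr1", "synthetic", "CDS",
                              g$cds[i, "start"], g$cds[i, "end"], ".",
                              g$strand, "0", attr0, sep = "\t"))
  }
  writeLines(lines, path)
}

#' Generate the synthetic reference bundle
#'
#' Writes a random genome with embedded multi-exon genes on both strands
#' (CDS plus UTRs), deliberate homopolymer runs beside artifact sites, a
#' repeat-mask BED, a mitochondrial contig, a dbSNP-style VCF holding the
#' planted germline SNPs, and a known-editing TSV listing the configured
#' fraction of editing sites. All planted site categories are disjoint by
#' position and recorded in the returned ground truth.
#'
#' @param cfg A `SimulationConfig`.
#' @param dir Output directory (created if needed).
#' @return list with `paths` (fasta, gtf, bed, vcf, known_editing),
#'   `truth` (class `GroundTruth`: data.frames `edits`, `snps`,
#'   `artifacts`), and `genes` (the gene models used).
#' @export
simulate_reference <- function(cfg, dir) {
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # --- gene structures laid left to right on chr1
  genes <- list()
  cursor <- 500L
  for (i in seq_len(cfg$n_genes)) {
    n_ex <- sample_int(2L, 4L)
    ex <- NULL
    start <- cursor
    for (e in seq_len(n_ex)) {
      len <- sample_int(200L, 400L)
      ex <- rbind(ex, c(start = start, end = start + len - 1L))
      start <- start + len + sample_int(200L, 500L)
    }
    spliced_len <- sum(ex[, "end"] - ex[, "start"] + 1L)
    u5 <- sample_int(50L, 90L); u3 <- sample_int(60L, 110L)
    cds_len <- 3L * ((spliced_len - u5 - u3) %/% 3L)
    if (cds_len < 30L) stop("gene too short for CDS; enlarge exons")
    strand <- if (i %% 2L == 1L) "+" else "-"
    if (strand == "+") {
      c1 <- u5 + 1L; c2 <- u5 + cds_len
    } else {
      c1 <- spliced_len - (u5 + cds_len) + 1L; c2 <- spliced_len - u5
    }
    cds <- spliced_to_genomic(ex, c1, c2)
    gid <- sprintf("gene%03d", i)
    genes[[gid]] <- list(gene_id = gid,
                         gene_name = sprintf("Gn%03d", i),
                         contig = "chr1", strand = strand, exons = ex,
                         cds = cds, biotype = "protein_coding")
    cursor <- max(ex[, "end"]) + sample_int(300L, 800L)
  }
  chr1_len <- cursor + 500L
  chrM_len <- 2000L
  chr1 <- sample(c("A", "C", "G", "T"), chr1_len, replace = TRUE)
  chrM <- sample(c("A", "C", "G", "T"), chrM_len, replace = TRUE)

  # --- junctions per gene (internal exon boundaries)
  all_junctions <- integer(0)
  for (g in genes) {
    ne <- nrow(g$exons)
    all_junctions <- c(all_junctions,
                       g$exons[-ne, "end"], g$exons[-1L, "start"])
  }
  all_junctions <- sort(all_junctions)
  jdist <- function(p) if (length(all_junctions) == 0L) Inf else
    min(abs(all_junctions - p))

  # --- candidate position pools
  far_pool <- NULL; near_pool <- NULL
  for (g in genes) {
    for (e in seq_len(nrow(g$exons))) {
      ps <- seq.int(g$exons[e, "start"] + 2L, g$exons[e, "end"] - 2L)
      d <- vapply(ps, jdist, 0)
      add <- function(pp) if (length(pp) > 0L)
        data.frame(pos = pp, gene_id = g$gene_id, strand = g$strand,
                   stringsAsFactors = FALSE) else NULL
      far_pool <- rbind(far_pool, add(ps[d >= 8]))
      near_pool <- rbind(near_pool, add(ps[d >= 2 & d <= 6]))
    }
  }

  accepted <- integer(0)
  pick <- function(pool, n, spacing = 16L) {
    if (n == 0L) return(pool[0L, , drop = FALSE])
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    taken <- NULL
    for (i in seq_len(nrow(pool))) {
      p <- pool$pos[i]
      if (length(accepted) == 0L || min(abs(accepted - p)) >= spacing) {
        taken <- rbind(taken, pool[i, , drop = FALSE])
        accepted <<- c(accepted, p)
        if (nrow(taken) == n) break
      }
    }
    if (is.null(taken) || nrow(taken) < n)
      stop("genome too small for requested features: needed ", n,
           " site(s), placed ", if (is.null(taken)) 0 else nrow(taken),
           "; increase n_genes")
    taken
  }

  n_edit_nj <- round(cfg$edit_near_junction_frac * cfg$n_edit_sites)
  near_junction_art <- pick(near_pool, cfg$n_artifact_near_junction)
  edit_nj <- if (n_edit_nj > 0L) pick(near_pool, n_edit_nj) else NULL
  homopoly <- pick(far_pool, cfg$n_artifact_homopolymer)
  strandbias <- pick(far_pool, cfg$n_artifact_strand_bias)
  het <- pick(far_pool, cfg$n_germline_het)
  hom <- pick(far_pool, cfg$n_germline_hom)
  diff <- pick(far_pool, cfg$n_diff_sites)
  edit_far <- pick(far_pool, cfg$n_edit_sites - n_edit_nj)
  background <- pick(far_pool, cfg$n_background)

  with_class <- function(df, cls) {
    if (is.null(df)) return(NULL)
    df$class <- rep(cls, nrow(df))
    df
  }
  planted <- rbind(
    with_class(near_junction_art, "near_junction"),
    with_class(edit_nj, "edit_near_junction"),
    with_class(homopoly, "homopolymer"),
    with_class(strandbias, "strand_bias"),
    with_class(het, "het"), with_class(hom, "hom"),
    with_class(diff, "diff"), with_class(edit_far, "edit"))

  # --- set reference base at planted sites (genomic G on + genes, C on -)
  for (i in seq_len(nrow(planted))) {
    p <- planted$pos[i]
    chr1[p] <- if (planted$strand[i] == "+") "G" else "C"
  }
  # homopolymer runs of 6 immediately right of the homopolymer artifacts
  hp <- planted$pos[planted$class == "homopolymer"]
  for (p in hp) chr1[(p + 1L):(p + 6L)] <- "T"
  # break accidental runs at every other planted site
  for (i in seq_len(nrow(planted))) {
    if (planted$class[i] == "homopolymer") next
    chr1 <- break_runs_at(chr1, planted$pos[i], protect = planted$pos)
  }
  # mitochondrial sites
  mito_pos <- if (cfg$n_mito_sites > 0L)
    seq(200L, by = 300L, length.out = cfg$n_mito_sites) else integer(0)
  chrM[mito_pos] <- "G"

  # --- ground truth tables
  alt_for <- function(strand) ifelse(strand == "+", "A", "T")
  is_edit <- planted$class %in% c("edit", "edit_near_junction", "diff")
  ed <- planted[is_edit, , drop = FALSE]
  n_null <- sum(ed$class != "diff")
  null_levels <- rep_len(cfg$edit_levels, n_null)
  edits <- data.frame(
    contig = rep("chr1", nrow(ed)), pos = ed$pos, gene_id = ed$gene_id,
    strand = ed$strand,
    ref = ifelse(ed$strand == "+", "G", "C"),
    alt = alt_for(ed$strand),
    diff = ed$class == "diff",
    near_junction = ed$class == "edit_near_junction",
    stringsAsFactors = FALSE)
  edits$level_control <- NA_real_
  edits$level_es <- NA_real_
  edits$level_ps <- NA_real_
  edits$level_control[!edits$diff] <- null_levels
  edits$level_es[!edits$diff] <- null_levels
  edits$level_ps[!edits$diff] <- null_levels
  edits$level_control[edits$diff] <- cfg$diff_levels["control"]
  edits$level_es[edits$diff] <- cfg$diff_levels["es"]
  edits$level_ps[edits$diff] <- cfg$diff_levels["ps"]
  n_known <- round(cfg$fraction_known * nrow(edits))
  known_idx <- if (n_known > 0L)
    sort(sample.int(nrow(edits), n_known)) else integer(0)
  edits$known <- seq_len(nrow(edits)) %in% known_idx

  sn <- planted[planted$class %in% c("het", "hom"), , drop = FALSE]
  snps <- data.frame(
    contig = rep("chr1", nrow(sn)), pos = sn$pos, gene_id = sn$gene_id,
    ref = ifelse(sn$strand == "+", "G", "C"),
    alt = alt_for(sn$strand),
    zygosity = ifelse(sn$class == "het", "het", "hom"),
    stringsAsFactors = FALSE)
  n_dbsnp <- round(cfg$fraction_dbsnp * nrow(snps))
  dbsnp_idx <- if (n_dbsnp > 0L)
    sort(sample.int(nrow(snps), n_dbsnp)) else integer(0)
  snps$in_dbsnp <- seq_len(nrow(snps)) %in% dbsnp_idx

  ar <- planted[planted$class %in%
                  c("near_junction", "homopolymer", "strand_bias"), ,
                drop = FALSE]
  artifacts <- data.frame(
    contig = c(rep("chr1", nrow(ar)), rep("chrM", length(mito_pos))),
    pos = c(ar$pos, mito_pos),
    ref = c(ifelse(ar$strand == "+", "G", "C"), rep("G", length(mito_pos))),
    alt = c(alt_for(ar$strand), rep("A", length(mito_pos))),
    class = c(ar$class, rep("mitochondrial", length(mito_pos))),
    stringsAsFactors = FALSE)

  bg <- data.frame(contig = rep("chr1", nrow(background)),
                   pos = background$pos, stringsAsFactors = FALSE)

  # --- write files
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gtf = file.path(dir, "genes.gtf"),
                bed = file.path(dir, "repeats.bed"),
                vcf = file.path(dir, "dbsnp.vcf"),
                known_editing = file.path(dir, "known_editing.tsv"))
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(chr1, collapse = ""),
                                     chrM = paste(chrM, collapse = "")))
  Biostrings::writeXStringSet(seqs, paths$fasta, width = 70L)
  write_gtf(genes, paths$gtf)
  # repeat intervals in intergenic space (BED: 0-based half-open)
  gaps_end <- vapply(genes, function(g) max(g$exons[, "end"]), 0)
  rep_start <- sort(gaps_end[seq_len(min(4L, length(gaps_end)))]) + 60L
  writeLines(paste("chr1", format(rep_start - 1L, scientific = FALSE,
                                  trim = TRUE),
                   format(rep_start + 39L, scientific = FALSE,
                          trim = TRUE),
                   sep = "\t"),
             paths$bed)
  vcf_rows <- snps[snps$in_dbsnp, , drop = FALSE]
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>", "##contig=<ID=chrM>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               if (nrow(vcf_rows) > 0L)
                 paste(vcf_rows$contig, vcf_rows$pos, ".", vcf_rows$ref,
                       vcf_rows$alt, ".", "PASS", ".", sep = "\t")),
             paths$vcf)
  ke <- edits[edits$known, , drop = FALSE]
  utils::write.table(
    data.frame(contig = ke$contig, pos = ke$pos, strand = ke$strand,
               type = rep("G-to-A", nrow(ke))),
    paths$known_editing, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- structure(list(edits = edits, snps = snps,
                          artifacts = artifacts, background = bg),
                     class = "GroundTruth")
  list(paths = paths, truth = truth, genes = genes)
}

phred_string <- function(q) intToUtf8(q + 33L)

emit_pileup_line <- function(contig, pos, ref, alt, level, depth, cfg,
                             strand_bias = FALSE) {
  n_alt <- stats::rbinom(1L, depth, level)
  base <- c(rep(alt, n_alt), rep(ref, depth - n_alt))
  is_alt_read <- c(rep(TRUE, n_alt), rep(FALSE, depth - n_alt))
  if (cfg$error_rate > 0) {
    err <- stats::runif(depth) < cfg$error_rate
    for (i in which(err))
      base[i] <- sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L)
  }
  fwd <- stats::runif(depth) < 0.5
  if (strand_bias) fwd[is_alt_read] <- TRUE
  q <- pmin(40L, pmax(2L, round(stats::rnorm(depth, cfg$qual_mean,
                                             cfg$qual_sd))))
  ord <- sample.int(depth)
  base <- base[ord]; fwd <- fwd[ord]; q <- q[ord]
  sym <- ifelse(base == ref, ifelse(fwd, ".", ","),
                ifelse(fwd, base, tolower(base)))
  starts <- stats::runif(depth) < cfg$read_mark_rate
  ends <- stats::runif(depth) < cfg$read_mark_rate
  sym <- paste0(ifelse(starts, "^~", ""), sym, ifelse(ends, "$", ""))
  paste(contig, pos, ref, depth, paste(sym, collapse = ""),
        phred_string(q), sep = "\t")
}

#' Generate per-sample pileup files for the synthetic study
#'
#' Every sample gets one mpileup file covering all planted sites plus the
#' background positions. Site depth is negative binomial; alternate reads
#' are binomial at the sample's true level (group level at editing sites,
#' 0.5/1.0 at het/hom SNPs, the artifact level at artifact sites); base
#' errors hit each read independently; strand-bias artifact sites put all
#' alternate reads on the forward strand.
#'
#' @param cfg A `SimulationConfig`.
#' @param ref Result of [simulate_reference()].
#' @param dir Output directory; pileups go to `dir`/pileups.
#' @return list with `sample_sheet` (sample_id, group, condition, role,
#'   pileup path) and `pileup_dir`.
#' @export
simulate_pileups <- function(cfg, ref, dir) {
  set.seed(cfg$seed + 1L)
  pdir <- file.path(dir, "pileups")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  truth <- ref$truth

  sheet <- rbind(
    if (cfg$n_control > 0L)
      data.frame(sample_id = sprintf("control_%d", seq_len(cfg$n_control)),
                 group = "control", condition = "control",
                 role = "discovery"),
    if (cfg$n_es > 0L)
      data.frame(sample_id = sprintf("es_%d", seq_len(cfg$n_es)),
                 group = "es", condition = "csds", role = "discovery"),
    if (cfg$n_ps > 0L)
      data.frame(sample_id = sprintf("ps_%d", seq_len(cfg$n_ps)),
                 group = "ps", condition = "csds", role = "discovery"),
    if (cfg$n_reference > 0L)
      data.frame(sample_id = sprintf("ref_%02d", seq_len(cfg$n_reference)),
                 group = "reference", condition = "reference",
                 role = "reference"))
  # paths are stored relative to the run directory so that identical
  # config + seed yield byte-identical files wherever the run lands
  sheet$pileup <- file.path("pileups", paste0(sheet$sample_id, ".pileup"))

  # site schedule shared by all samples, sorted by contig then position
  ed <- truth$edits
  snp_lv <- ifelse(truth$snps$zygosity == "het", 0.5, 1)
  n_art <- nrow(truth$artifacts)
  n_bg <- nrow(truth$background)
  sites <- rbind(
    data.frame(contig = ed$contig, pos = ed$pos, ref = ed$ref,
               alt = ed$alt, level_control = ed$level_control,
               level_es = ed$level_es, level_ps = ed$level_ps,
               strand_bias = rep(FALSE, nrow(ed)),
               stringsAsFactors = FALSE),
    data.frame(contig = truth$snps$contig, pos = truth$snps$pos,
               ref = truth$snps$ref, alt = truth$snps$alt,
               level_control = snp_lv, level_es = snp_lv,
               level_ps = snp_lv,
               strand_bias = rep(FALSE, nrow(truth$snps)),
               stringsAsFactors = FALSE),
    data.frame(contig = truth$artifacts$contig, pos = truth$artifacts$pos,
               ref = truth$artifacts$ref, alt = truth$artifacts$alt,
               level_control = rep(cfg$artifact_level, n_art),
               level_es = rep(cfg$artifact_level, n_art),
               level_ps = rep(cfg$artifact_level, n_art),
               strand_bias = truth$artifacts$class == "strand_bias",
               stringsAsFactors = FALSE),
    data.frame(contig = truth$background$contig,
               pos = truth$background$pos,
               ref = rep(NA_character_, n_bg), alt = rep("A", n_bg),
               level_control = rep(0, n_bg), level_es = rep(0, n_bg),
               level_ps = rep(0, n_bg),
               strand_bias = rep(FALSE, n_bg), stringsAsFactors = FALSE))
  # reference base at background sites from the genome
  genome <- load_reference(ref$paths$fasta)
  na_ref <- is.na(sites$ref)
  sites$ref[na_ref] <- vapply(which(na_ref), function(i)
    genome_base(genome, sites$contig[i], sites$pos[i]), "")
  bg_alt <- sites$ref[na_ref] == "A"
  sites$alt[na_ref][bg_alt] <- "G"
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]

  for (s in seq_len(nrow(sheet))) {
    grp <- sheet$group[s]
    lv <- switch(grp,
                 control = sites$level_control,
                 es = sites$level_es,
                 ps = sites$level_ps,
                 reference = sites$level_control)
    lines <- character(0)
    for (i in seq_len(nrow(sites))) {
      depth <- stats::rnbinom(1L, size = cfg$depth_size,
                              mu = cfg$depth_mean)
      if (depth == 0L) next
      lines <- c(lines, emit_pileup_line(
        sites$contig[i], sites$pos[i], sites$ref[i], sites$alt[i],
        lv[i], depth, cfg, strand_bias = sites$strand_bias[i]))
    }
    writeLines(lines, file.path(dir, sheet$pileup[s]))
  }
  list(sample_sheet = sheet, pileup_dir = pdir)
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_reference()] and [simulate_pileups()], writes the
#' ground-truth tables, sample sheet and a manifest recording the
#' configuration and seed.
#'
#' @param cfg A `SimulationConfig`.
#' @param dir Run directory.
#' @return list with `paths`, `truth`, `genes`, `sample_sheet`, `cfg`.
#' @export
simulate_study <- function(cfg = simulation_config(),
                           dir = tempfile("gaedit_study_")) {
  ref <- simulate_reference(cfg, dir)
  pu <- simulate_pileups(cfg, ref, dir)
  utils::write.table(ref$truth$edits, file.path(dir, "truth_edits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$truth$artifacts,
                     file.path(dir, "truth_artifacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pu$sample_sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scal <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 1L,
                     TRUE)]
  writeLines(c("# synthetic study manifest",
               paste0(names(scal), ": ", unlist(scal))),
             file.path(dir, "manifest.yaml"))
  list(dir = dir, paths = ref$paths, truth = ref$truth,
       genes = ref$genes, sample_sheet = pu$sample_sheet, cfg = cfg)
}

#' Score pipeline output against the planted ground truth
#'
#' Site discovery is matched by exact (contig, position). Differential
#' calls are scored on the planted shifted sites (sensitivity) and the
#' planted non-shifted editing sites (false-positive rate).
#'
#' @param truth A `GroundTruth`.
#' @param hcs A `HighConfidenceSet`.
#' @param diff Optional data.frame from [compare_groups()] (needs
#'   contig, pos, significant, testable columns).
#' @param level_min Sensitivity is reported for planted sites whose
#'   maximum group level is at least this (default 0.1).
#' @return data.frame(metric, value, numerator, denominator).
#' @export
evaluate_recovery <- function(truth, hcs, diff = NULL, level_min = 0.1) {
  ev_keys <- paste(hcs$events$contig, hcs$events$pos, sep = ":")
  ed <- truth$edits
  ed_keys <- paste(ed$contig, ed$pos, sep = ":")
  lv_max <- pmax(ed$level_control, ed$level_es, ed$level_ps)
  det <- ed_keys[lv_max >= level_min]
  sens_num <- sum(det %in% ev_keys)
  fp_num <- sum(!ev_keys %in% ed_keys)
  sn_keys <- paste(truth$snps$contig, truth$snps$pos, sep = ":")
  snp_kept <- sum(sn_keys %in% ev_keys)
  out <- data.frame(
    metric = c("site_sensitivity", "site_fdr", "snp_removal"),
    value = c(if (length(det) > 0) sens_num / length(det) else NA,
              if (length(ev_keys) > 0) fp_num / length(ev_keys) else 0,
              if (length(sn_keys) > 0)
                1 - snp_kept / length(sn_keys) else NA),
    numerator = c(sens_num, fp_num, length(sn_keys) - snp_kept),
    denominator = c(length(det), length(ev_keys), length(sn_keys)),
    stringsAsFactors = FALSE)
  if (!is.null(diff)) {
    dk <- paste(diff$contig, diff$pos, sep = ":")
    shifted <- ed_keys[ed$diff]
    null_keys <- ed_keys[!ed$diff]
    sig <- dk[diff$significant %in% TRUE]
    tested_null <- sum(null_keys %in% dk[diff$testable %in% TRUE])
    out <- rbind(out, data.frame(
      metric = c("diff_sensitivity", "diff_fpr"),
      value = c(if (length(shifted) > 0)
                  sum(shifted %in% sig) / length(shifted) else NA,
                if (tested_null > 0)
                  sum(null_keys %in% sig) / tested_null else NA),
      numerator = c(sum(shifted %in% sig), sum(null_keys %in% sig)),
      denominator = c(length(shifted), tested_null),
      stringsAsFactors = FALSE))
  }
  out
}
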