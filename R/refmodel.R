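#' Load a reference genome from FASTA
#'
#' Reads all records of a FASTA file into an in-memory genome object.
#' Sequences are uppercased; `N` is allowed. Contigs whose names are in
#' `mito_names` are treated as mitochondrial by the filter cascade.
#'
#' @param fasta_path Path to a FASTA file.
#' @param mito_names Character vector of contig names considered
#'   mitochondrial (default `c("chrM", "MT")`).
#' @return An object of class `ReferenceGenome`: a list with `contigs`
#'   (named character vector of uppercase sequences) and `mito_names`.
#' @export
load_reference <- function(fasta_path, mito_names = c("chrM", "MT")) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  # read without alphabet coercion so that invalid residue codes are
  # rejected here instead of silently dropped
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("FASTA parse error in ", fasta_path, ": ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0L) stop("no records in FASTA file: ", fasta_path)
  contigs <- toupper(as.character(seqs))
  # first word of the header is the contig name
  names(contigs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) with non-ACGTN characters: ",
         paste(names(contigs)[bad], collapse = ", "))
  structure(list(contigs = contigs, mito_names = mito_names),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp total\n")
  invisible(x)
}

genome_base <- function(genome, contig, pos) {
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (pos < 1L || pos > nchar(seq))
    stop("position ", pos, " out of bounds for contig ", contig,
         " (length ", nchar(seq), ")")
  substr(seq, pos, pos)
}

#' Length of the homopolymer run at or immediately beside a position
#'
#' Returns the length of the longest maximal single-nucleotide run that
#' contains `pos` or lies within `adjacency` bases of it. A substitution
#' call at the edge of a long run is a classic alignment artifact, so the
#' cascade flags sites adjacent to runs as well as sites inside them.
#'
#' @param genome A `ReferenceGenome`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @param adjacency How many bases to either side are considered "beside"
#'   the position (default 1).
#' @return Integer run length (>= 1).
#' @export
homopolymer_run_length <- function(genome, contig, pos, adjacency = 1L) {
  seq <- genome$contigs[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  n <- nchar(seq)
  if (pos < 1L || pos > n)
    stop("position ", pos, " out of bounds for contig ", contig)
  run_len_at <- function(i) {
    ch <- substr(seq, i, i)
    l <- i
    while (l > 1L && substr(seq, l - 1L, l - 1L) == ch) l <- l - 1L
    r <- i
    while (r < n && substr(seq, r + 1L, r + 1L) == ch) r <- r + 1L
    r - l + 1L
  }
  probe <- seq.int(max(1L, pos - adjacency), min(n, pos + adjacency))
  max(vapply(probe, run_len_at, integer(1)))
}

parse_gtf_attr <- function(attrs, key) {
  # rtracklayer handles this; kept for the simulator's writer round-trip
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  ifelse(lengths(m) > 0, sub(paste0(key, ' "([^"]*)"'), "\\1", m), NA_character_)
}

#' Load gene annotation from GTF
#'
#' Builds one gene model per `gene_id` from gene/exon/CDS features and
#' derives splice-junction positions: every internal exon boundary (end of
#' exon i, start of exon i+1) of a multi-exon gene is a junction;
#' single-exon genes contribute none.
#'
#' @param gtf_path Path to a GTF file with `gene_id` (and optionally
#'   `gene_name`, `gene_biotype`) attributes on exon and CDS features.
#' @return An object of class `AnnotationSet`: list with `genes` (named
#'   list of gene models), `gene_index` (a `GRanges` of gene spans) and
#'   `junctions` (per-contig sorted integer vectors of junction positions).
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"gene_id" %in% names(df)) stop("GTF has no gene_id attributes")
  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(feat) == 0L) stop("GTF has no exon features")
  genes <- list()
  for (gid in unique(feat$gene_id)) {
    g <- feat[feat$gene_id == gid, , drop = FALSE]
    strand <- as.character(unique(g$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("gene ", gid, ": strand must be exactly one of +/- (got ",
           paste(strand, collapse = "/"), ")")
    contig <- as.character(unique(g$seqnames))
    if (length(contig) != 1L) stop("gene ", gid, " spans multiple contigs")
    ex <- g[g$type == "exon", c("start", "end"), drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0L) stop("gene ", gid, " has no exons")
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("gene ", gid, ": exons overlap")
    cds <- g[g$type == "CDS", c("start", "end"), drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      inside <- any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
      if (!inside)
        stop("gene ", gid, ": CDS interval [", cds$start[i], ",", cds$end[i],
             "] not contained in any exon")
    }
    gname <- if ("gene_name" %in% names(g) && !all(is.na(g$gene_name)))
      g$gene_name[!is.na(g$gene_name)][1] else gid
    btype <- if ("gene_biotype" %in% names(g) && !all(is.na(g$gene_biotype)))
      g$gene_biotype[!is.na(g$gene_biotype)][1] else "protein_coding"
    genes[[gid]] <- list(
      gene_id = gid, gene_name = gname, contig = contig, strand = strand,
      exons = as.matrix(ex), cds = as.matrix(cds), biotype = btype)
  }
  gene_index <- GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, "", "contig"),
    ranges = IRanges::IRanges(
      start = vapply(genes, function(g) min(g$exons[, "start"]), 0),
      end = vapply(genes, function(g) max(g$exons[, "end"]), 0)),
    gene_id = names(genes))
  junctions <- list()
  for (g in genes) {
    ne <- nrow(g$exons)
    if (ne < 2L) next
    j <- c(g$exons[-ne, "end"], g$exons[-1L, "start"])
    junctions[[g$contig]] <- c(junctions[[g$contig]], j)
  }
  junctions <- lapply(junctions, function(v) sort(unique(as.integer(v))))
  structure(list(genes = genes, gene_index = gene_index,
                 junctions = junctions),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$genes), "gene(s),",
      sum(lengths(x$junctions)), "splice junction position(s)\n")
  invisible(x)
}

#' Distance from a position to the nearest splice junction
#'
#' @param ann An `AnnotationSet`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @return Minimum absolute distance (integer >= 0) to any junction
#'   position on the contig, or `NA` when the contig has no junctions.
#' @export
distance_to_splice_junction <- function(ann, contig, pos) {
  j <- ann$junctions[[contig]]
  if (is.null(j) || length(j) == 0L) return(NA_integer_)
  as.integer(min(abs(j - pos)))
}

#' Genes overlapping a position
#'
#' A position is genic when it falls inside some gene's exonic span
#' (min exon start to max exon end); introns count as genic. An empty
#' result means intergenic.
#'
#' @param ann An `AnnotationSet`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @return data.frame with columns gene_id, gene_name, strand, sorted by
#'   gene_id (zero rows when intergenic).
#' @export
classify_genic <- function(ann, contig, pos) {
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  # querying a contig absent from the index is an ordinary miss
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, ann$gene_index, ignore.strand = TRUE))
  ids <- ann$gene_index$gene_id[S4Vectors::subjectHits(hits)]
  ids <- sort(ids)
  data.frame(
    gene_id = ids,
    gene_name = vapply(ids, function(i) ann$genes[[i]]$gene_name, ""),
    strand = vapply(ids, function(i) ann$genes[[i]]$strand, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

in_interval <- function(mat, pos) {
  nrow(mat) > 0L && any(mat[, "start"] <= pos & pos <= mat[, "end"])
}

revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}

spliced_sequence <- function(genome, contig, ivs) {
  seq <- genome$contigs[[contig]]
  paste(vapply(seq_len(nrow(ivs)),
               function(i) substr(seq, ivs[i, "start"], ivs[i, "end"]), ""),
        collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Coding consequence of a single-base substitution within a gene
#'
#' For CDS positions the codon is rebuilt from the spliced CDS sequence
#' (reverse-complemented for minus-strand genes), the alternate base is
#' substituted, and both codons are translated with the standard genetic
#' code. Exonic non-CDS positions are classified as 5'UTR/3'UTR relative
#' to the CDS in transcript orientation, or as non-coding-exon for genes
#' without CDS. Everything else inside the gene span is intron.
#'
#' @param genome A `ReferenceGenome`.
#' @param gene A gene model from an `AnnotationSet` (`ann$genes[[id]]`).
#' @param pos 1-based genomic position inside the gene span.
#' @param ref_allele Single reference base; must match the genome at `pos`.
#' @param alt_allele Single alternate base.
#' @return One of "missense", "synonymous", "stop-gain", "stop-lost",
#'   "5'UTR", "3'UTR", "non-coding-exon", "intron".
#' @export
annotate_consequence <- function(genome, gene, pos, ref_allele, alt_allele) {
  stopifnot(nchar(ref_allele) == 1L, nchar(alt_allele) == 1L)
  gbase <- genome_base(genome, gene$contig, pos)
  if (gbase != ref_allele)
    stop("reference discordance at ", gene$contig, ":", pos,
         " (genome ", gbase, ", call ", ref_allele, ")")
  in_exon <- in_interval(gene$exons, pos)
  has_cds <- nrow(gene$cds) > 0L
  if (!in_exon) return("intron")
  if (!has_cds) return("non-coding-exon")
  if (!in_interval(gene$cds, pos)) {
    cds_lo <- min(gene$cds[, "start"]); cds_hi <- max(gene$cds[, "end"])
    if (gene$strand == "+") {
      return(if (pos < cds_lo) "5'UTR" else "3'UTR")
    } else {
      return(if (pos > cds_hi) "5'UTR" else "3'UTR")
    }
  }
  # spliced CDS coordinate of pos (genomic order)
  cds <- gene$cds
  offset <- 0L
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, "start"] && pos <= cds[i, "end"]) {
      offset <- offset + (pos - cds[i, "start"] + 1L)
      break
    }
    offset <- offset + (cds[i, "end"] - cds[i, "start"] + 1L)
  }
  cds_seq <- spliced_sequence(genome, gene$contig, cds)
  cds_len <- nchar(cds_seq)
  if (cds_len %% 3L != 0L)
    stop("gene ", gene$gene_id, ": CDS length ", cds_len,
         " is not a multiple of 3")
  if (gene$strand == "-") {
    cds_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    tx_pos <- cds_len - offset + 1L
    alt_tx <- revcomp_base(alt_allele)
  } else {
    tx_pos <- offset
    alt_tx <- alt_allele
  }
  ci <- (tx_pos - 1L) %/% 3L          # 0-based codon index
  off <- (tx_pos - 1L) %% 3L + 1L     # 1..3 within codon
  codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_tx
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*") return("stop-gain")
  if (aa_ref == "*") return("stop-lost")
  "missense"
}

#' Load a simple-repeat mask from BED
#'
#' @param bed_path BED3 file (0-based half-open, converted on import).
#' @return A `GRanges` of repeat intervals (1-based closed).
#' @export
load_repeat_mask <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  info <- file.info(bed_path)
  if (is.na(info$size) || info$size == 0L)
    return(GenomicRanges::GRanges())
  rtracklayer::import(bed_path, format = "bed")
}

#' Is a position inside the repeat mask?
#' @param mask `GRanges` from [load_repeat_mask()].
#' @param contig Contig name.
#' @param pos 1-based position.
#' @return logical.
#' @export
in_repeat <- function(mask, contig, pos) {
  if (length(mask) == 0L) return(FALSE)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  length(suppressWarnings(
    GenomicRanges::findOverlaps(q, mask, ignore.strand = TRUE))) > 0L
}

#' Load known germline variants from a sites-only VCF
#'
#' Membership is exact on (contig, position, ref allele, alt allele): a
#' known A>C polymorphism at a position does not disqualify a G>A editing
#' candidate there.
#'
#' @param vcf_path VCF v4.x file.
#' @return An object of class `KnownVariantSet`.
#' @export
load_known_variants <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  keys <- character(0)
  if (length(rr) > 0L) {
    contig <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    alt_list <- rr$ALT
    n_alt <- lengths(alt_list)
    keys <- paste(rep(contig, n_alt), rep(pos, n_alt), rep(ref, n_alt),
                  as.character(unlist(alt_list)), sep = ":")
  }
  structure(list(keys = unique(keys)), class = "KnownVariantSet")
}

#' @param kv A `KnownVariantSet`.
#' @param contig,pos,ref,alt Variant key parts.
#' @return logical: exact membership.
#' @rdname load_known_variants
#' @export
known_variant <- function(kv, contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":") %in% kv$keys
}

#' Load a table of known RNA editing sites
#'
#' Tab-separated with header columns contig, pos, strand, type. Membership
#' is by (contig, position) only: catalogued editing sites are reported on
#' the transcript strand, so allele matching is not attempted.
#'
#' @param tsv_path Path to the TSV.
#' @return An object of class `KnownEditingSet`.
#' @export
load_known_editing <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("known-editing TSV not found: ", tsv_path)
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "strand", "type")
  if (!all(need %in% names(tab)))
    stop("known-editing TSV must have columns: ", paste(need, collapse = ", "))
  structure(list(table = tab,
                 keys = unique(paste(tab$contig, tab$pos, sep = ":"))),
            class = "KnownEditingSet")
}

#' @param ke A `KnownEditingSet`.
#' @param contig,pos Site key parts.
#' @return logical: positional membership.
#' @rdname load_known_editing
#' @export
known_editing <- function(ke, contig, pos) {
  paste(contig, pos, sep = ":") %in% ke$keys
}

#' Assemble the reference bundle queried by the filter cascade
#'
#' @param fasta_path,gtf_path,bed_path,vcf_path,editing_tsv_path Paths to
#'   the genome FASTA, gene-annotation GTF, repeat-mask BED, known-variant
#'   VCF and known-editing TSV.
#' @param mito_names Contig names treated as mitochondrial.
#' @return An object of class `ReferenceBundle` with elements `genome`,
#'   `annotation`, `repeats`, `known_variants`, `known_editing`.
#' @export
reference_bundle <- function(fasta_path, gtf_path, bed_path, vcf_path,
                             editing_tsv_path,
                             mito_names = c("chrM", "MT")) {
  structure(list(
    genome = load_reference(fasta_path, mito_names = mito_names),
    annotation = load_annotation(gtf_path),
    repeats = load_repeat_mask(bed_path),
    known_variants = load_known_variants(vcf_path),
    known_editing = load_known_editing(editing_tsv_path)),
    class = "ReferenceBundle")
}
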