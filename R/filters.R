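#' Filter-cascade configuration
#'
#' Thresholds of the six-rule artifact/germline cascade and the admission
#' rule for high-confidence events. Defaults follow the discovery
#' criteria: homopolymer runs >= 5 nt, splice-junction distance <= 6 nt,
#' INDEL distance <= 1 nt, the germline allele-frequency pattern (> 90% of
#' samples at AAF = 100% or within [40%, 60%]), replication level >= 1%,
#' and detection in >= 2 discovery samples.
#'
#' @param homopolymer_min_run Minimum run length that flags a site.
#' @param splice_max_dist Maximum distance to a splice junction that flags
#'   a site (inclusive).
#' @param indel_max_dist Maximum distance to a same-sample INDEL call that
#'   flags a site (inclusive).
#' @param germline_sample_frac Fraction of callable samples above which
#'   the AAF genotype pattern removes a site (strictly greater than).
#' @param het_band Two-element numeric, the heterozygote AAF band
#'   (inclusive).
#' @param hom_value AAF counted as homozygous.
#' @param replication_min_level Minimum editing level for reference-cohort
#'   replication.
#' @param min_discovery_samples Minimum discovery samples for the
#'   multi-sample admission route.
#' @param germline_denominator "callable" (samples with qualifying depth;
#'   default) or "all" (every discovery sample).
#' @return A list of class `CascadeConfig`.
#' @export
cascade_config <- function(homopolymer_min_run = 5L, splice_max_dist = 6L,
                           indel_max_dist = 1L,
                           germline_sample_frac = 0.90,
                           het_band = c(0.40, 0.60), hom_value = 1.00,
                           replication_min_level = 0.01,
                           min_discovery_samples = 2L,
                           germline_denominator = c("callable", "all")) {
  stopifnot(homopolymer_min_run >= 1, splice_max_dist >= 0,
            indel_max_dist >= 0, germline_sample_frac > 0,
            germline_sample_frac <= 1, length(het_band) == 2L,
            het_band[1] <= het_band[2], het_band[1] >= 0, het_band[2] <= 1,
            hom_value >= 0, hom_value <= 1, replication_min_level > 0,
            replication_min_level <= 1, min_discovery_samples >= 1)
  structure(list(homopolymer_min_run = as.integer(homopolymer_min_run),
                 splice_max_dist = as.integer(splice_max_dist),
                 indel_max_dist = as.integer(indel_max_dist),
                 germline_sample_frac = germline_sample_frac,
                 het_band = het_band, hom_value = hom_value,
                 replication_min_level = replication_min_level,
                 min_discovery_samples = as.integer(min_discovery_samples),
                 germline_denominator = match.arg(germline_denominator)),
            class = "CascadeConfig")
}

#' Edit type of a substitution in transcript orientation
#'
#' For genes on the plus strand the type is "ref-to-alt" verbatim; for
#' minus-strand genes both alleles are complemented first, so a genomic
#' C>T inside a minus-strand gene is a transcript "G-to-A".
#'
#' @param ref_allele,alt_allele Single genomic bases.
#' @param gene_strand "+" or "-".
#' @return Edit-type string such as "G-to-A".
#' @export
classify_edit_type <- function(ref_allele, alt_allele, gene_strand) {
  stopifnot(gene_strand %in% c("+", "-"))
  if (gene_strand == "-") {
    ref_allele <- revcomp_base(ref_allele)
    alt_allele <- revcomp_base(alt_allele)
  }
  paste0(ref_allele, "-to-", alt_allele)
}

#' Germline allele-frequency pattern filter
#'
#' Removes a site when more than `germline_sample_frac` of the callable
#' discovery samples have an AAF equal to `hom_value` or inside
#' `het_band` — the signature of a germline genotype rather than editing.
#' Samples without qualifying coverage (`NA` level) are excluded from the
#' denominator under the default "callable" mode.
#'
#' @param levels Numeric vector of per-sample AAFs across all discovery
#'   samples; `NA` marks a sample without qualifying coverage.
#' @param cfg A `CascadeConfig`.
#' @return logical: `TRUE` means remove.
#' @export
germline_pattern_filter <- function(levels, cfg = cascade_config()) {
  eps <- 1e-9
  callable <- !is.na(levels)
  n <- if (cfg$germline_denominator == "callable") sum(callable)
       else length(levels)
  if (sum(callable) == 0L || n == 0L) return(FALSE)
  lv <- levels[callable]
  pat <- abs(lv - cfg$hom_value) <= eps |
    (lv >= cfg$het_band[1] - eps & lv <= cfg$het_band[2] + eps)
  sum(pat) / n > cfg$germline_sample_frac
}

site_filter_flags <- function(contig, pos, ref_allele, alt_allele, levels,
                              indel_positions, bundle, cfg) {
  c(repeat_or_homopolymer =
      in_repeat(bundle$repeats, contig, pos) ||
      homopolymer_run_length(bundle$genome, contig, pos) >=
        cfg$homopolymer_min_run,
    mitochondrial = contig %in% bundle$genome$mito_names,
    near_splice = {
      d <- distance_to_splice_junction(bundle$annotation, contig, pos)
      !is.na(d) && d <= cfg$splice_max_dist
    },
    near_indel = length(indel_positions) > 0L &&
      any(abs(indel_positions - pos) <= cfg$indel_max_dist),
    dbsnp_known = known_variant(bundle$known_variants, contig, pos,
                                ref_allele, alt_allele),
    germline_pattern = germline_pattern_filter(levels, cfg))
}

#' Apply the six site-level filters to one editing candidate
#'
#' Flags are computed independently: (1) simple repeat or homopolymer run,
#' (2) mitochondrial contig, (3) splice-junction proximity, (4) same-sample
#' INDEL proximity, (5) known germline variant (exact allele match),
#' (6) germline AAF pattern. A site present in the known-editing catalogue
#' is rescued: all six flags are voided.
#'
#' @param cand A list/row with contig, pos, ref_allele, alt_allele and a
#'   `levels` numeric vector (per discovery sample, `NA` = no coverage).
#' @param bundle A `ReferenceBundle`.
#' @param indel_positions Integer vector of INDEL-call positions on the
#'   candidate's contig in the samples where the candidate was called.
#' @param cfg A `CascadeConfig`.
#' @return `cand` with `filter_flags` (named logical), `rescued`, and
#'   `clean` (no effective flags) added.
#' @export
apply_site_filters <- function(cand, bundle, indel_positions = integer(0),
                               cfg = cascade_config()) {
  flags <- site_filter_flags(cand$contig, cand$pos, cand$ref_allele,
                             cand$alt_allele, cand$levels,
                             indel_positions, bundle, cfg)
  cand$rescued <- known_editing(bundle$known_editing, cand$contig, cand$pos)
  cand$filter_flags <- flags
  cand$clean <- cand$rescued || !any(flags)
  cand
}

summary_index <- function(sc) {
  s <- sc$summaries
  idx <- seq_len(nrow(s))
  names(idx) <- paste(s$contig, s$pos, sep = ":")
  idx
}

level_at <- function(sc, idx, contig, pos, alt, min_depth) {
  i <- idx[[paste(contig, pos, sep = ":")]]
  if (is.null(i)) return(NA_real_)
  row <- sc$summaries[i, ]
  if (row$qdepth < min_depth) return(NA_real_)
  row[[alt]] / row$qdepth
}

#' Build the high-confidence G-to-A editing event set
#'
#' Pools post-filter SNV calls across discovery samples into candidates,
#' applies the six-rule cascade with known-editing rescue, restricts to
#' genic sites whose transcript-strand edit type is G-to-A, and admits
#' candidates detected in at least `min_discovery_samples` discovery
#' samples or replicated in at least one reference-cohort sample at a
#' level of at least `replication_min_level`. Detection is sample-level
#' (a qualifying call survives the false-positive filter); the six flags
#' are site-level.
#'
#' @param discovery List of `SampleCalls` for the discovery samples.
#' @param cohort List of `SampleCalls` for the reference cohort (may be
#'   empty).
#' @param bundle A `ReferenceBundle`.
#' @param cfg A `CascadeConfig`.
#' @param thr The `CallThresholds` used for calling (supplies the depth
#'   below which a sample is not callable at a site).
#' @param edit_type Transcript-strand edit type to admit.
#' @return An object of class `HighConfidenceSet`: list with `events`
#'   (admitted candidates), `candidates` (every pooled candidate with
#'   flags and diagnostics), `levels` (candidate x discovery-sample matrix
#'   of editing levels, `NA` = not callable), `samples`, `config`.
#' @export
build_high_confidence_set <- function(discovery, cohort = list(), bundle,
                                      cfg = cascade_config(),
                                      thr = call_thresholds(),
                                      edit_type = "G-to-A") {
  if (length(discovery) == 0L) stop("no samples")
  disc_ids <- vapply(discovery, `[[`, "", "sample_id")
  names(discovery) <- disc_ids
  pooled <- do.call(rbind, lapply(discovery, function(sc)
    sc$calls[sc$calls$kind == "SNV" & sc$calls$fp_pass, , drop = FALSE]))
  rownames(pooled) <- NULL
  cohort_snv <- if (length(cohort) > 0L) {
    do.call(rbind, lapply(cohort, function(sc)
      sc$calls[sc$calls$kind == "SNV" & sc$calls$fp_pass, , drop = FALSE]))
  } else empty_calls()
  idx <- lapply(discovery, summary_index)

  if (nrow(pooled) == 0L) {
    res <- structure(list(events = empty_candidates(),
                          candidates = empty_candidates(),
                          levels = matrix(numeric(0), 0, length(disc_ids),
                                          dimnames = list(NULL, disc_ids)),
                          samples = disc_ids, config = cfg),
                     class = "HighConfidenceSet")
    return(res)
  }

  key <- paste(pooled$contig, pooled$pos, pooled$ref_allele,
               pooled$alt_allele, sep = ":")
  ckey <- if (nrow(cohort_snv) > 0L)
    paste(cohort_snv$contig, cohort_snv$pos, cohort_snv$ref_allele,
          cohort_snv$alt_allele, sep = ":") else character(0)
  ukeys <- unique(key)
  rows <- vector("list", length(ukeys))
  lv_mat <- matrix(NA_real_, length(ukeys), length(disc_ids),
                   dimnames = list(ukeys, disc_ids))
  for (k in seq_along(ukeys)) {
    sub <- pooled[key == ukeys[k], , drop = FALSE]
    contig <- sub$contig[1]; pos <- sub$pos[1]
    ref <- sub$ref_allele[1]; alt <- sub$alt_allele[1]
    called_in <- unique(sub$sample_id)
    levels <- vapply(disc_ids, function(sid)
      level_at(discovery[[sid]], idx[[sid]], contig, pos, alt,
               thr$min_depth), 0)
    lv_mat[k, ] <- levels
    genes <- classify_genic(bundle$annotation, contig, pos)
    strands <- unique(genes$strand)
    strand_ambiguous <- length(strands) > 1L
    etype <- if (nrow(genes) == 0L) NA_character_
      else if (strand_ambiguous) "strand-ambiguous"
      else classify_edit_type(ref, alt, strands)
    indel_pos <- integer(0)
    for (sid in called_in) {
      cs <- discovery[[sid]]$calls
      ind <- cs[cs$kind %in% c("INS", "DEL") & cs$contig == contig, ,
                drop = FALSE]
      indel_pos <- c(indel_pos, ind$pos)
    }
    cand <- apply_site_filters(
      list(contig = contig, pos = pos, ref_allele = ref, alt_allele = alt,
           levels = levels),
      bundle, indel_positions = indel_pos, cfg = cfg)
    n_cohort <- sum(ckey == ukeys[k] &
                      cohort_snv$aaf >= cfg$replication_min_level)
    gene_id <- if (nrow(genes) > 0L) genes$gene_id[1] else NA_character_
    consequence <- NA_character_
    if (!is.na(gene_id) && etype %in% edit_type) {
      consequence <- annotate_consequence(
        bundle$genome, bundle$annotation$genes[[gene_id]], pos, ref, alt)
    }
    admitted <- cand$clean && nrow(genes) > 0L &&
      !is.na(etype) && etype == edit_type &&
      (length(called_in) >= cfg$min_discovery_samples || n_cohort >= 1L)
    provenance <- if (!admitted) NA_character_ else {
      multi <- length(called_in) >= cfg$min_discovery_samples
      repl <- n_cohort >= 1L
      if (multi && repl) "both" else if (multi) "multi_sample"
      else "replication"
    }
    flags <- cand$filter_flags
    rows[[k]] <- data.frame(
      contig = contig, pos = pos, ref_allele = ref, alt_allele = alt,
      edit_type = etype, gene_id = gene_id,
      gene_ids = paste(genes$gene_id, collapse = ","),
      strand_ambiguous = strand_ambiguous,
      consequence = consequence,
      n_discovery = length(called_in), n_cohort = n_cohort,
      flag_repeat_or_homopolymer = unname(flags["repeat_or_homopolymer"]),
      flag_mitochondrial = unname(flags["mitochondrial"]),
      flag_near_splice = unname(flags["near_splice"]),
      flag_near_indel = unname(flags["near_indel"]),
      flag_dbsnp_known = unname(flags["dbsnp_known"]),
      flag_germline_pattern = unname(flags["germline_pattern"]),
      rescued = cand$rescued, clean = cand$clean,
      genic = nrow(genes) > 0L,
      admitted = admitted, provenance = provenance,
      stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, rows)
  rownames(candidates) <- NULL
  structure(list(events = candidates[candidates$admitted, , drop = FALSE],
                 candidates = candidates,
                 levels = lv_mat,
                 samples = disc_ids, config = cfg),
            class = "HighConfidenceSet")
}

empty_candidates <- function() {
  data.frame(contig = character(0), pos = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             edit_type = character(0), gene_id = character(0),
             gene_ids = character(0), strand_ambiguous = logical(0),
             consequence = character(0), n_discovery = integer(0),
             n_cohort = integer(0),
             flag_repeat_or_homopolymer = logical(0),
             flag_mitochondrial = logical(0), flag_near_splice = logical(0),
             flag_near_indel = logical(0), flag_dbsnp_known = logical(0),
             flag_germline_pattern = logical(0), rescued = logical(0),
             clean = logical(0), genic = logical(0), admitted = logical(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' @export
print.HighConfidenceSet <- function(x, ...) {
  cat("HighConfidenceSet:", nrow(x$events), "event(s) admitted of",
      nrow(x$candidates), "candidate(s) across", length(x$samples),
      "discovery sample(s)\n")
  invisible(x)
}

#' Count high-confidence events per gene
#'
#' Each event is attributed to a single gene (the alphabetically first
#' gene_id when several overlap, a deterministic tie-break).
#'
#' @param hcs A `HighConfidenceSet`.
#' @return data.frame(gene_id, n_events), sorted by decreasing count then
#'   gene_id.
#' @export
aggregate_per_gene <- function(hcs) {
  ev <- hcs$events
  ev <- ev[!is.na(ev$gene_id), , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(gene_id = character(0), n_events = integer(0)))
  tab <- table(ev$gene_id)
  out <- data.frame(gene_id = names(tab), n_events = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_events, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Editing-level matrix of the admitted events
#'
#' @param hcs A `HighConfidenceSet`.
#' @param sample_sheet data.frame(sample_id, group) covering the discovery
#'   samples.
#' @return An object of class `EditingMatrix`: list with `events`
#'   (data.frame key columns), `samples` (the sheet), `levels` (events x
#'   samples matrix, `NA` = not callable).
#' @export
editing_matrix <- function(hcs, sample_sheet) {
  stopifnot(all(c("sample_id", "group") %in% names(sample_sheet)))
  missing <- setdiff(sample_sheet$sample_id, hcs$samples)
  if (length(missing) > 0L)
    stop("sample(s) absent from call set: ", paste(missing, collapse = ", "))
  ev <- hcs$events
  keys <- paste(ev$contig, ev$pos, ev$ref_allele, ev$alt_allele, sep = ":")
  lv <- hcs$levels[keys, sample_sheet$sample_id, drop = FALSE]
  new_editing_matrix(lv, ev[, c("contig", "pos", "ref_allele",
                                "alt_allele", "gene_id")], sample_sheet)
}

#' Construct an `EditingMatrix` from components
#'
#' @param levels Events x samples numeric matrix of fractions in \[0, 1\]
#'   (`NA` allowed).
#' @param events data.frame with at least contig, pos, ref_allele,
#'   alt_allele.
#' @param sample_sheet data.frame(sample_id, group) in column order of
#'   `levels`.
#' @return An `EditingMatrix`.
#' @export
new_editing_matrix <- function(levels, events, sample_sheet) {
  levels <- as.matrix(levels)
  stopifnot(nrow(levels) == nrow(events),
            ncol(levels) == nrow(sample_sheet))
  vals <- levels[!is.na(levels)]
  if (length(vals) > 0L && (min(vals) < 0 || max(vals) > 1))
    stop("editing levels must lie in [0, 1]")
  rownames(levels) <- paste(events$contig, events$pos, events$ref_allele,
                            events$alt_allele, sep = ":")
  colnames(levels) <- sample_sheet$sample_id
  structure(list(events = events, samples = sample_sheet, levels = levels),
            class = "EditingMatrix")
}

#' @export
print.EditingMatrix <- function(x, ...) {
  cat("EditingMatrix:", nrow(x$levels), "event(s) x", ncol(x$levels),
      "sample(s); groups:",
      paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' Write the event table as TSV
#' @param hcs A `HighConfidenceSet`.
#' @param path Output path.
#' @param what "events" (default) or "candidates".
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(hcs, path, what = c("events", "candidates")) {
  what <- match.arg(what)
  tab <- hcs[[what]]
  keys <- paste(tab$contig, tab$pos, tab$ref_allele, tab$alt_allele,
                sep = ":")
  lv <- hcs$levels[keys, , drop = FALSE]
  colnames(lv) <- paste0("level_", colnames(lv))
  utils::write.table(cbind(tab, as.data.frame(lv)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write admitted events as a sites-only VCF
#' @param hcs A `HighConfidenceSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_vcf <- function(hcs, path) {
  ev <- hcs$events
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Attributed gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "##INFO=<ID=PROV,Number=1,Type=String,Description=\"Admission route\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(ev) > 0L) {
    paste(ev$contig, ev$pos, ".", ev$ref_allele, ev$alt_allele, ".",
          "PASS",
          sprintf("GENE=%s;CSQ=%s;PROV=%s", ev$gene_id, ev$consequence,
                  ev$provenance),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
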