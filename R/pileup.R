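#' Variant-calling thresholds
#'
#' Defaults follow the discovery criteria used throughout the package:
#' base quality >= 25, quality-filtered sequencing depth >= 10, alternative
#' allele depth >= 2 and alternative allele frequency (AAF) >= 1%. All
#' comparisons are inclusive.
#'
#' @param q_min Minimum Phred base quality for an observation to count.
#' @param min_depth Minimum quality-filtered depth at the site.
#' @param min_alt_depth Minimum quality-filtered alternate-allele depth.
#' @param min_aaf Minimum alternate allele frequency, in (0, 1].
#' @return A list of class `CallThresholds`.
#' @export
call_thresholds <- function(q_min = 25L, min_depth = 10L,
                            min_alt_depth = 2L, min_aaf = 0.01) {
  stopifnot(q_min >= 0, min_depth >= 0, min_alt_depth >= 0,
            min_aaf > 0, min_aaf <= 1)
  structure(list(q_min = as.integer(q_min),
                 min_depth = as.integer(min_depth),
                 min_alt_depth = as.integer(min_alt_depth),
                 min_aaf = min_aaf),
            class = "CallThresholds")
}

#' Parse one samtools mpileup line (6-column dialect)
#'
#' Tokenizes the base string: `.`/`,` are reference observations on the
#' forward/reverse strand; `ACGTN`/`acgtn` alternate observations by
#' strand; `^X` (read start plus mapping quality) and `$` (read end) are
#' consumed; `+N<seq>`/`-N<seq>` insertions/deletions are attached to the
#' preceding base observation; `*` is a deletion placeholder that counts
#' toward depth but is no allele observation.
#'
#' @param line One mpileup record (tab-separated, 6 columns).
#' @return A list of class `PileupSite` with fields contig, pos, ref_base,
#'   depth and an `obs` data.frame (base, fwd, qual, indel).
#' @export
parse_pileup_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 6L)
    stop("pileup parse error: expected 6 columns, got ", length(f),
         " in line: ", substr(line, 1, 60))
  contig <- f[1]
  pos <- as.integer(f[2])
  ref <- toupper(f[3])
  depth <- as.integer(f[4])
  bases <- f[5]
  quals <- f[6]
  # strip read-start (with its mapping-quality char) and read-end marks;
  # neither consumes a base-quality character
  b <- gsub("\\^.", "", bases)
  b <- gsub("$", "", b, fixed = TRUE)
  if (grepl("[+-]", b)) {
    chars0 <- strsplit(b, "", fixed = TRUE)[[1]]
    sym <- character(0)
    indel <- character(0)
    i <- 1L
    n <- length(chars0)
    while (i <= n) {
      ch <- chars0[i]
      if (ch == "+" || ch == "-") {
        if (length(sym) == 0L)
          stop("pileup parse error at ", contig, ":", pos,
               ": indel token with no preceding base")
        j <- i + 1L
        while (j <= n && grepl("[0-9]", chars0[j])) j <- j + 1L
        len <- as.integer(paste(chars0[(i + 1L):(j - 1L)], collapse = ""))
        if (is.na(len) || j + len - 1L > n)
          stop("pileup parse error at ", contig, ":", pos,
               ": malformed indel token")
        seq <- paste(chars0[j:(j + len - 1L)], collapse = "")
        indel[length(indel)] <- paste0(ch, toupper(seq))
        i <- j + len
      } else {
        sym <- c(sym, ch)
        indel <- c(indel, NA_character_)
        i <- i + 1L
      }
    }
  } else {
    sym <- strsplit(b, "", fixed = TRUE)[[1]]
    indel <- rep(NA_character_, length(sym))
  }
  qchars <- strsplit(quals, "", fixed = TRUE)[[1]]
  if (length(sym) != depth || length(qchars) != depth)
    stop("pileup parse error at ", contig, ":", pos, ": ", length(sym),
         " base symbol(s), ", length(qchars), " quality char(s), depth ",
         depth)
  fwd <- !(sym %in% c(",", letters) | sym %in% c("a", "c", "g", "t", "n"))
  fwd[sym == "*"] <- NA
  base <- toupper(sym)
  base[sym == "."] <- ref
  base[sym == ","] <- ref
  obs <- data.frame(base = base, fwd = fwd,
                    qual = utf8ToInt(quals) - 33L,
                    indel = indel, stringsAsFactors = FALSE)
  structure(list(contig = contig, pos = pos, ref_base = ref,
                 depth = depth, obs = obs),
            class = "PileupSite")
}

#' Summarize a pileup site at a base-quality cutoff
#'
#' Only observations with Phred quality >= `q_min` are counted. The `*`
#' deletion placeholder contributes to the quality-filtered depth but to
#' no allele count.
#'
#' @param site A `PileupSite` from [parse_pileup_line()].
#' @param q_min Minimum base quality.
#' @return A list of class `SiteSummary`: contig, pos, ref_base, qdepth,
#'   per-base counts/strand-splits/mean qualities, and an `indels`
#'   data.frame (allele, count, fwd, rev, mean_qual).
#' @export
summarize_site <- function(site, q_min = 25L) {
  obs <- site$obs[site$obs$qual >= q_min, , drop = FALSE]
  qdepth <- nrow(obs)
  alleles <- c("A", "C", "G", "T", "N")
  count <- fwd <- rev_ <- integer(length(alleles))
  meanq <- rep(NA_real_, length(alleles))
  names(count) <- names(fwd) <- names(rev_) <- names(meanq) <- alleles
  for (a in alleles) {
    sel <- obs$base == a
    count[a] <- sum(sel)
    fwd[a] <- sum(sel & obs$fwd %in% TRUE)
    rev_[a] <- sum(sel & obs$fwd %in% FALSE)
    if (count[a] > 0L) meanq[a] <- mean(obs$qual[sel])
  }
  idx <- !is.na(obs$indel)
  if (any(idx)) {
    ind <- obs[idx, , drop = FALSE]
    indels <- do.call(rbind, lapply(split(ind, ind$indel), function(d) {
      data.frame(allele = d$indel[1], count = nrow(d),
                 fwd = sum(d$fwd %in% TRUE), rev = sum(d$fwd %in% FALSE),
                 mean_qual = mean(d$qual), stringsAsFactors = FALSE)
    }))
    rownames(indels) <- NULL
  } else {
    indels <- data.frame(allele = character(0), count = integer(0),
                         fwd = integer(0), rev = integer(0),
                         mean_qual = numeric(0))
  }
  structure(list(contig = site$contig, pos = site$pos,
                 ref_base = site$ref_base, qdepth = qdepth,
                 count = count, fwd = fwd, rev = rev_, mean_qual = meanq,
                 indels = indels),
            class = "SiteSummary")
}

variant_call_row <- function(sample_id, summ, alt, alt_depth, aaf, kind,
                             alt_fwd, alt_rev, alt_q) {
  ref <- summ$ref_base
  data.frame(
    sample_id = sample_id, contig = summ$contig, pos = summ$pos,
    ref_allele = ref, alt_allele = alt, kind = kind,
    total_depth = summ$qdepth, alt_depth = alt_depth, aaf = aaf,
    alt_fwd = alt_fwd, alt_rev = alt_rev,
    ref_fwd = unname(summ$fwd[ref]), ref_rev = unname(summ$rev[ref]),
    mean_q_alt = alt_q, mean_q_ref = unname(summ$mean_qual[ref]),
    stringsAsFactors = FALSE)
}

#' Call single-nucleotide variants at a summarized site
#'
#' One call per non-reference base passing all of: quality-filtered depth
#' >= `min_depth`, alternate depth >= `min_alt_depth`, and AAF >=
#' `min_aaf`, where AAF = alternate depth / quality-filtered depth.
#'
#' @param summ A `SiteSummary`.
#' @param thr A `CallThresholds`.
#' @param sample_id Sample identifier recorded on each call.
#' @return data.frame of calls (possibly zero rows).
#' @export
call_variants <- function(summ, thr = call_thresholds(),
                          sample_id = "sample") {
  out <- list()
  if (summ$qdepth >= thr$min_depth) {
    for (a in c("A", "C", "G", "T")) {
      if (a == summ$ref_base) next
      ad <- unname(summ$count[a])
      if (ad < thr$min_alt_depth) next
      aaf <- ad / summ$qdepth
      if (aaf < thr$min_aaf) next
      out[[length(out) + 1L]] <- variant_call_row(
        sample_id, summ, a, ad, aaf, "SNV",
        unname(summ$fwd[a]), unname(summ$rev[a]),
        unname(summ$mean_qual[a]))
    }
  }
  if (length(out) == 0L) return(empty_calls())
  do.call(rbind, out)
}

#' Call insertions/deletions at a summarized site
#'
#' Applies the same depth/alt-depth/AAF thresholds as SNV calling.
#' Deletions are anchored at the base before the deleted run, as in the
#' mpileup notation itself.
#'
#' @inheritParams call_variants
#' @return data.frame of calls with kind INS/DEL (possibly zero rows).
#' @export
call_indels <- function(summ, thr = call_thresholds(),
                        sample_id = "sample") {
  out <- list()
  if (summ$qdepth >= thr$min_depth && nrow(summ$indels) > 0L) {
    for (i in seq_len(nrow(summ$indels))) {
      ad <- summ$indels$count[i]
      if (ad < thr$min_alt_depth) next
      aaf <- ad / summ$qdepth
      if (aaf < thr$min_aaf) next
      allele <- summ$indels$allele[i]
      kind <- if (substr(allele, 1, 1) == "+") "INS" else "DEL"
      out[[length(out) + 1L]] <- variant_call_row(
        sample_id, summ, allele, ad, aaf, kind,
        summ$indels$fwd[i], summ$indels$rev[i], summ$indels$mean_qual[i])
    }
  }
  if (length(out) == 0L) return(empty_calls())
  do.call(rbind, out)
}

empty_calls <- function() {
  data.frame(sample_id = character(0), contig = character(0),
             pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), kind = character(0),
             total_depth = integer(0), alt_depth = integer(0),
             aaf = numeric(0), alt_fwd = integer(0), alt_rev = integer(0),
             ref_fwd = integer(0), ref_rev = integer(0),
             mean_q_alt = numeric(0), mean_q_ref = numeric(0),
             stringsAsFactors = FALSE)
}

#' False-positive filter on a variant call
#'
#' Emulates the two pileup-computable checks of VarScan-style
#' false-positive filtering: (a) strand bias — all alternate observations
#' on one strand while reference observations occur on both, with
#' alternate depth >= `strand_min`; (b) the mean alternate base quality
#' falling more than `q_diff_max` below the mean reference base quality.
#'
#' @param call One row of a call data.frame.
#' @param strand_min Minimum alternate depth for the strand check
#'   (default 4).
#' @param q_diff_max Maximum tolerated ref-minus-alt mean-quality gap
#'   (default 10).
#' @return list(pass = logical, reasons = character vector of
#'   machine-readable codes among "strand_bias", "low_alt_quality").
#' @export
false_positive_filter <- function(call, strand_min = 4L, q_diff_max = 10) {
  reasons <- character(0)
  one_strand <- (call$alt_fwd == 0L || call$alt_rev == 0L)
  ref_both <- (call$ref_fwd > 0L && call$ref_rev > 0L)
  if (one_strand && ref_both && call$alt_depth >= strand_min)
    reasons <- c(reasons, "strand_bias")
  if (!is.na(call$mean_q_alt) && !is.na(call$mean_q_ref) &&
      call$mean_q_alt < call$mean_q_ref - q_diff_max)
    reasons <- c(reasons, "low_alt_quality")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Call variants for one sample's pileup file
#'
#' Parses every record, summarizes it at the quality cutoff, calls SNVs
#' and INDELs, and applies the false-positive filter. Per-site summaries
#' are returned alongside the calls because downstream steps need editing
#' levels at sites where a sample has coverage but no call.
#'
#' @param pileup_path Path to a single-sample mpileup text file.
#' @param thr A `CallThresholds`.
#' @param sample_id Sample identifier.
#' @return list of class `SampleCalls`: `calls` (post-filter SNV/INDEL
#'   data.frame with fp columns), `summaries` (per-site data.frame of
#'   quality-filtered counts), `sample_id`.
#' @export
call_sample <- function(pileup_path, thr = call_thresholds(),
                        sample_id = sub("\\.pileup$", "", basename(pileup_path))) {
  if (!file.exists(pileup_path)) stop("pileup file not found: ", pileup_path)
  lines <- readLines(pileup_path)
  lines <- lines[nzchar(lines)]
  calls <- list()
  summ_rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    site <- parse_pileup_line(lines[k])
    summ <- summarize_site(site, q_min = thr$q_min)
    summ_rows[[k]] <- data.frame(
      contig = summ$contig, pos = summ$pos, ref_base = summ$ref_base,
      qdepth = summ$qdepth,
      A = unname(summ$count["A"]), C = unname(summ$count["C"]),
      G = unname(summ$count["G"]), T = unname(summ$count["T"]),
      stringsAsFactors = FALSE)
    cl <- rbind(call_variants(summ, thr, sample_id),
                call_indels(summ, thr, sample_id))
    if (nrow(cl) > 0L) calls[[length(calls) + 1L]] <- cl
  }
  calls <- if (length(calls) > 0L) do.call(rbind, calls) else empty_calls()
  if (nrow(calls) > 0L) {
    fp <- lapply(seq_len(nrow(calls)),
                 function(i) false_positive_filter(calls[i, , drop = FALSE]))
    calls$fp_pass <- vapply(fp, `[[`, TRUE, "pass")
    calls$fp_reason <- vapply(fp, function(x)
      paste(x$reasons, collapse = ";"), "")
  } else {
    calls$fp_pass <- logical(0)
    calls$fp_reason <- character(0)
  }
  structure(list(sample_id = sample_id, calls = calls,
                 summaries = do.call(rbind, summ_rows)),
            class = "SampleCalls")
}

#' Write calls as a sites-only VCF
#'
#' INFO carries DP (quality-filtered depth), AD (alternate depth) and AF;
#' FILTER carries PASS or the false-positive reason codes.
#'
#' @param calls A call data.frame (with fp columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Quality-filtered depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate allele depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  snvs <- calls[calls$kind == "SNV", , drop = FALSE]
  filt <- if (nrow(snvs) > 0L && "fp_pass" %in% names(snvs)) {
    ifelse(snvs$fp_pass, "PASS",
           gsub(";", ",", snvs$fp_reason, fixed = TRUE))
  } else rep("PASS", nrow(snvs))
  body <- if (nrow(snvs) > 0L) {
    paste(snvs$contig, snvs$pos, ".", snvs$ref_allele, snvs$alt_allele,
          ".", filt,
          sprintf("DP=%d;AD=%d;AF=%.6g", snvs$total_depth, snvs$alt_depth,
                  snvs$aaf),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
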