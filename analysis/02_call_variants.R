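#!/usr/bin/env Rscript
# Per-sample variant calling from the study pileups: quality-filtered
# pileup summaries, SNV/INDEL calls at the discovery thresholds
# (Q >= 25, depth >= 10, alt >= 2, AAF >= 1%), and the false-positive
# filter. Writes one call table and one sites-only VCF per sample under
# results/calls/.
#
#   Rscript analysis/02_call_variants.R [study_dir] [out_dir]

suppressMessages(library(gaedit))
args <- commandArgs(trailingOnly = TRUE)
study_dir <- if (length(args) >= 1) args[1] else "results/synthetic_study"
out_dir <- if (length(args) >= 2) args[2] else "results/calls"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sheet <- load_sample_sheet(study_dir)
thr <- call_thresholds()
for (i in seq_len(nrow(sheet))) {
  sc <- call_sample(sheet$pileup[i], thr = thr,
                    sample_id = sheet$sample_id[i])
  write.table(sc$calls,
              file.path(out_dir, paste0(sheet$sample_id[i], "_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_calls_vcf(sc$calls,
                  file.path(out_dir, paste0(sheet$sample_id[i], ".vcf")))
  cat(sprintf("%-12s %4d SNV calls (%d pass fp-filter), %d INDEL calls\n",
              sheet$sample_id[i], sum(sc$calls$kind == "SNV"),
              sum(sc$calls$kind == "SNV" & sc$calls$fp_pass),
              sum(sc$calls$kind != "SNV")))
}
cat("call tables written to", out_dir, "\n")
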