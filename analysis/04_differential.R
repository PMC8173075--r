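#!/usr/bin/env Rscript
# Differential editing analysis on the high-confidence events:
# Student's t-tests of editing levels (control vs CSDS and ES vs PS,
# p < 0.05, no multiple-testing correction), detection overlap between
# the conditions, and PCA of the significant events. Writes
# differential_*.tsv, pca_scores.tsv and overlap.tsv under results/.
#
#   Rscript analysis/04_differential.R [study_dir] [out_dir]

suppressMessages(library(gaedit))
args <- commandArgs(trailingOnly = TRUE)
study_dir <- if (length(args) >= 1) args[1] else "results/synthetic_study"
out_dir <- if (length(args) >= 2) args[2] else "results"

run_path <- file.path(out_dir, "pipeline_run.rds")
run <- if (file.exists(run_path)) readRDS(run_path) else
  run_editing_pipeline(study_dir)

comparisons <- list(
  control_vs_csds = list(group_by = "condition", g1 = "control",
                         g2 = "csds"),
  es_vs_ps = list(group_by = "group", g1 = "es", g2 = "ps"))
for (nm in names(comparisons)) {
  cmp <- comparisons[[nm]]
  mat <- pipeline_matrix(run, group_by = cmp$group_by)
  diff <- compare_groups(mat, cmp$g1, cmp$g2)
  write.table(diff, file.path(out_dir, paste0("differential_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- which(diff$significant %in% TRUE)
  cat(sprintf("%s: %d of %d testable events significant (%d up in %s, %d up in %s)\n",
              nm, length(sig), sum(diff$testable),
              sum(diff$direction[sig] == "up"), cmp$g2,
              sum(diff$direction[sig] == "down"), cmp$g1))
  if (nm == "control_vs_csds" && length(sig) >= 2) {
    sub <- new_editing_matrix(mat$levels[sig, , drop = FALSE],
                              mat$events[sig, , drop = FALSE],
                              mat$samples)
    pc <- pca_events(sub)
    cat(sprintf("  PCA of the %d significant events: PC1 explains %.1f%% of variance\n",
                length(sig), 100 * pc$var_explained[1]))
    scores <- data.frame(sample_id = rownames(pc$scores),
                         group = mat$samples$group, pc$scores[, 1:2])
    write.table(scores, file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
}

# detection overlap of admitted events between control and CSDS samples
hcs <- run$hcs
ev_keys <- paste(hcs$events$contig, hcs$events$pos,
                 hcs$events$ref_allele, hcs$events$alt_allele)
detected_in <- function(samples) {
  pooled <- do.call(rbind, lapply(run$discovery, function(s)
    s$calls[s$calls$fp_pass & s$calls$kind == "SNV" &
              s$calls$sample_id %in% samples, , drop = FALSE]))
  keys <- paste(pooled$contig, pooled$pos, pooled$ref_allele,
                pooled$alt_allele)
  unique(keys[keys %in% ev_keys])
}
disc <- run$sheet[run$sheet$role == "discovery", ]
ov <- detection_overlap(
  detected_in(disc$sample_id[disc$condition == "control"]),
  detected_in(disc$sample_id[disc$condition == "csds"]))
cat(sprintf("detection overlap: %d shared (%.1f%%), %d control-only, %d CSDS-only\n",
            ov$shared, 100 * ov$frac_shared, ov$a_only, ov$b_only))
write.table(data.frame(ov), file.path(out_dir, "overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
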