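#!/usr/bin/env Rscript
# High-confidence G-to-A event identification: pools the per-sample
# calls, applies the six-rule artifact/germline cascade with
# known-editing rescue, restricts to genic transcript-strand G-to-A
# sites and admits events detected in >= 2 discovery samples or
# replicated in the reference cohort at level >= 1%. Scores recovery
# against the planted truth. Writes events.tsv, events.vcf,
# candidates.tsv, gene_counts.tsv and recovery.tsv under results/.
#
#   Rscript analysis/03_identify_events.R [study_dir] [out_dir]

suppressMessages(library(gaedit))
args <- commandArgs(trailingOnly = TRUE)
study_dir <- if (length(args) >= 1) args[1] else "results/synthetic_study"
out_dir <- if (length(args) >= 2) args[2] else "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

run <- run_editing_pipeline(study_dir)
saveRDS(run, file.path(out_dir, "pipeline_run.rds"))  # reused by 04/05

hcs <- run$hcs
write_events_tsv(hcs, file.path(out_dir, "events.tsv"))
write_events_tsv(hcs, file.path(out_dir, "candidates.tsv"),
                 what = "candidates")
write_events_vcf(hcs, file.path(out_dir, "events.vcf"))
genes <- aggregate_per_gene(hcs)
write.table(genes, file.path(out_dir, "gene_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- list(edits = read.delim(file.path(study_dir, "truth_edits.tsv")),
              snps = read.delim(file.path(study_dir, "truth_snps.tsv")),
              artifacts = read.delim(file.path(study_dir,
                                               "truth_artifacts.tsv")))
class(truth) <- "GroundTruth"
rec <- evaluate_recovery(truth, hcs)
write.table(rec, file.path(out_dir, "recovery.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d candidates admitted as high-confidence events in %d genes\n",
            nrow(hcs$events), nrow(hcs$candidates), nrow(genes)))
cat("admission route:\n")
print(table(hcs$events$provenance))
cat("consequence classes:\n")
print(table(hcs$events$consequence))
cat("recovery against planted truth:\n")
print(rec, row.names = FALSE)
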