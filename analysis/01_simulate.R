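#!/usr/bin/env Rscript
# Generate the synthetic editing study: a 3/3/3 discovery design
# (control / emotional stress / physical stress) plus an 8-sample
# reference cohort, with planted editing sites, germline SNPs and
# alignment artifacts. Writes the reference bundle, per-sample pileups
# and ground-truth tables under results/synthetic_study/.
#
#   Rscript analysis/01_simulate.R [seed] [study_dir]

suppressMessages(library(gaedit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
study_dir <- if (length(args) >= 2) args[2] else "results/synthetic_study"

cfg <- simulation_config(seed = seed)
st <- simulate_study(cfg, study_dir)

cat("study written to", st$dir, "\n")
cat(sprintf("  %d discovery + %d reference-cohort samples\n",
            sum(st$sample_sheet$role == "discovery"),
            sum(st$sample_sheet$role == "reference")))
cat(sprintf("  %d editing sites (%d differential), %d germline SNPs, %d artifact sites\n",
            nrow(st$truth$edits), sum(st$truth$edits$diff),
            nrow(st$truth$snps), nrow(st$truth$artifacts)))
cat(sprintf("  %d sites listed in the known-editing catalogue\n",
            sum(st$truth$edits$known)))
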