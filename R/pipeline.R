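#' Load the reference bundle of a (synthetic or real) study directory
#'
#' Expects the file layout written by [simulate_study()]: reference.fa,
#' genes.gtf, repeats.bed, dbsnp.vcf, known_editing.tsv.
#'
#' @param dir Study directory.
#' @return A `ReferenceBundle`.
#' @export
load_study_bundle <- function(dir) {
  reference_bundle(file.path(dir, "reference.fa"),
                   file.path(dir, "genes.gtf"),
                   file.path(dir, "repeats.bed"),
                   file.path(dir, "dbsnp.vcf"),
                   file.path(dir, "known_editing.tsv"))
}

#' Read the sample sheet of a study directory
#' @param dir Study directory containing samples.tsv.
#' @return data.frame(sample_id, group, condition, role, pileup).
#' @export
load_sample_sheet <- function(dir) {
  sheet <- utils::read.delim(file.path(dir, "samples.tsv"),
                             stringsAsFactors = FALSE)
  rel <- !file.exists(sheet$pileup)
  sheet$pileup[rel] <- file.path(dir, sheet$pileup[rel])
  sheet
}

#' Run the editing-discovery pipeline on a study directory
#'
#' Calls variants in every sample's pileup, applies the false-positive
#' filter, runs the six-rule cascade with known-editing rescue, and
#' admits high-confidence G-to-A events by the multi-sample /
#' replication rule. Discovery and reference-cohort samples are taken
#' from the sheet's `role` column.
#'
#' @param dir Study directory (layout of [simulate_study()]).
#' @param thr A `CallThresholds`.
#' @param cfg A `CascadeConfig`.
#' @param bundle Optional pre-loaded `ReferenceBundle` (loaded from `dir`
#'   when missing).
#' @return list: `hcs` (`HighConfidenceSet`), `discovery`/`cohort`
#'   (per-sample `SampleCalls`), `sheet`, `bundle`, `thr`, `cfg`.
#' @export
run_editing_pipeline <- function(dir, thr = call_thresholds(),
                                 cfg = cascade_config(), bundle = NULL) {
  sheet <- load_sample_sheet(dir)
  if (is.null(bundle)) bundle <- load_study_bundle(dir)
  call_one <- function(i) call_sample(sheet$pileup[i], thr = thr,
                                      sample_id = sheet$sample_id[i])
  disc_idx <- which(sheet$role == "discovery")
  coh_idx <- which(sheet$role == "reference")
  discovery <- lapply(disc_idx, call_one)
  cohort <- lapply(coh_idx, call_one)
  hcs <- build_high_confidence_set(discovery, cohort, bundle,
                                   cfg = cfg, thr = thr)
  list(hcs = hcs, discovery = discovery, cohort = cohort, sheet = sheet,
       bundle = bundle, thr = thr, cfg = cfg)
}

#' Editing matrix of a pipeline run, with chosen group labels
#'
#' @param run Result of [run_editing_pipeline()].
#' @param group_by Sheet column used as the group label: "group"
#'   (control/es/ps) or "condition" (control/csds).
#' @return An `EditingMatrix` over the discovery samples.
#' @export
pipeline_matrix <- function(run, group_by = c("group", "condition")) {
  group_by <- match.arg(group_by)
  disc <- run$sheet[run$sheet$role == "discovery", , drop = FALSE]
  sheet <- data.frame(sample_id = disc$sample_id,
                      group = disc[[group_by]],
                      stringsAsFactors = FALSE)
  editing_matrix(run$hcs, sheet)
}
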