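#!/usr/bin/env Rscript
# Runs the synthetic test-retest cohort study (two scans per subject,
# artifacts drawn with the configured prevalences, corrections applied,
# quantitation per scan) and writes the descriptive tables: artifact
# frequencies, myocardial relative differences, misalignment offsets,
# lung-volume test-retest and polar-map scores.
#
# Usage: Rscript analysis/04_study.R [n_subjects] [seed]

suppressPackageStartupMessages(library(dixonac))
args <- commandArgs(trailingOnly = TRUE)
n <- if (length(args) >= 1) as.integer(args[1]) else 3L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

out_dir <- "results/study"
cfg <- cohort_config(n_subjects = n)
cat(sprintf("Running %d subjects x 2 scans at %s, seed %d ...\n",
            n, paste(cfg$grid_shape, collapse = "x"), seed))
study <- run_study(cfg, seed = seed)
tabs <- summarize_study(study)
write_study_tables(tabs, out_dir)

cat("\nArtifact frequencies (subjects affected):\n")
print(tabs$frequency, row.names = FALSE)
cat("\nMyocardial relative differences by artifact type:\n")
print(tabs$rd, row.names = FALSE)
cat("\nMisalignment summary:\n")
print(tabs$misalignment, row.names = FALSE)
cat("\nLung-volume test-retest:\n")
print(tabs$lung, row.names = FALSE)
cat("\nPolar-map scores (original vs corrected maps):\n")
print(tabs$polar, row.names = FALSE)

ledgers <- do.call(rbind, lapply(study$subjects,
                                 function(s) s$artifact_ledger))
if (!is.null(ledgers))
  write.csv(ledgers, file.path(out_dir, "artifact_ledger.csv"),
            row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, n_subjects = n,
       scans = tabs$scans), file.path(out_dir, "study_report.json"),
  auto_unbox = TRUE, digits = NA, dataframe = "rows")
cat("\nTables written to", out_dir, "\n")
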