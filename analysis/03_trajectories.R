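#!/usr/bin/env Rscript
# Stage 3: variant trajectories and patient evolution patterns.
#
# Classifies each retained variant between the paired samples (acquired /
# lost / expanded / declined / stable; expansion and decline require both a
# significant two-proportion test and |delta VAF| >= 0.10), derives the
# patient-level pattern, parallel-evolution events, clonality transitions
# and the pathway / druggable-gene summaries.

suppressPackageStartupMessages(library(mmclonetrack))

cohort <- load_cohort_dir("results/cohort")
res <- run_cascade(cohort, filter_config())
traj <- classify_trajectory(res$retained, trajectory_config())
patterns <- classify_patient_pattern(traj)
parallel <- detect_parallel_evolution(traj)
summaries <- summarize_pathways_and_druggable(
  traj, druggable_lists = default_druggable_lists())

dir.create("results/evolution", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(traj, "results/evolution/trajectories.tsv", na = ".")
readr::write_tsv(patterns, "results/evolution/patterns.tsv", na = ".")
readr::write_tsv(parallel, "results/evolution/parallel_evolution.tsv", na = ".")
readr::write_tsv(summaries$pathways, "results/evolution/pathways.tsv", na = ".")
readr::write_tsv(summaries$druggable, "results/evolution/druggable.tsv", na = ".")

cat("Trajectory classes:\n"); print(table(traj$trajectory_class))
cat("Evolution patterns:\n"); print(table(patterns$pattern))
cat("Clonal (subclonal -> clonal) transitions:",
    sum(traj$clonal_transition), "\n")
cat("Parallel-evolution events:", nrow(parallel), "\n")

# recovery against ground truth, when stage 1's truth tables are present
if (file.exists("results/truth/truth_patients.tsv")) {
  tp <- readr::read_tsv("results/truth/truth_patients.tsv", na = ".",
                        show_col_types = FALSE)
  m <- merge(patterns, tp, by = "patient_id")
  cat(sprintf("Pattern recovery vs truth: %.1f%%\n",
              100 * mean(m$pattern.x == m$pattern.y)))
}
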