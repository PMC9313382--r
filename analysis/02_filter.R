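#!/usr/bin/env Rscript
# Stage 2: the variant inclusion cascade.
#
# Applies population-AF < 1%, VAF >= 10% with >= 5 reads in at least one of
# the paired samples, pathogenic consensus in >= 2 of six predictors (with
# the recurrent-gene cancer-predictor exception), and benign/likely-benign
# ACMG rejection with the KMT2C c.1173C>A whitelist.

suppressPackageStartupMessages(library(mmclonetrack))

cohort <- load_cohort_dir("results/cohort")
val <- validate_cohort(cohort)
stopifnot(attr(val, "ok"))

res <- run_cascade(cohort, filter_config())

dir.create("results/filter", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(res$report, "results/filter/filter_report.tsv")
readr::write_tsv(res$retained, "results/filter/retained_variants.tsv", na = ".")

cat("Filter cascade:\n")
print(as.data.frame(res$report))
cat(nrow(res$retained), "retained (patient, variant) units\n")
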