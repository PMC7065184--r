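#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 20 single-classifier reference tumours per molecular class plus 20
# multiple-classifier queries per combination (MMRd-p53abn, POLEmut-p53abn),
# written as the file set the downstream stages read: surrogate-marker
# sample sheet, MAF-like SNV table, SEG copy-number table, survival table,
# and the generating truth table.

library(mcec)

cfg <- cohort_config(seed = 17)
cohort <- generate_cohort(cfg)
paths <- write_cohort(cohort, "results/cohort")

cat("Simulated", nrow(cohort$samples), "tumours:",
    sum(cohort$truth$sample_type == "reference"), "references,",
    sum(cohort$truth$sample_type == "query"), "multiple-classifier queries\n")
cat("SNV rows:", nrow(cohort$snv), " segment rows:", nrow(cohort$seg), "\n")
cat("Median SNV burden by class:\n")
print(tapply(cohort$truth$n_snv, cohort$truth$true_class, median))
cat("Written to:", dirname(paths[1]), "\n")
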