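#!/usr/bin/env Rscript
# Stage 8: score the pipeline against the planted truth.
#
# Sensitivity and precision per call type: up/down regulation per layer,
# planted concordance classes, operon polarity per layer, and novel ORF
# discovery/validation.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
res <- run_full(bundle)
metrics <- evaluate_against_truth(res, bundle)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(metrics, "results/tables/recovery_metrics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(metrics, digits = 3)
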