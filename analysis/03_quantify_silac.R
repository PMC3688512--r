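#!/usr/bin/env Rscript
# Stage 3: heavy-standard SILAC protein quantification.
#
# Peptide H/L ratios, per-replicate protein ratios (log-scale median, two
# ratio counts minimum), direct ratios (the heavy standard cancels),
# replicate t-tests with Benjamini-Hochberg correction, and the
# incorporation-rate estimate from the heavy-only run.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
silac <- quantify_silac(bundle$evidence)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(silac$proteins, "results/tables/protein_quant.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(silac$incorporation$per_protein,
            "results/tables/incorporation_per_protein.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

quant <- sum(is.finite(silac$proteins$direct_log2))
cat(sprintf("proteins with direct ratios: %d\n", quant))
cat(sprintf("up: %d, down: %d (BH-adjusted p < 0.05, |log2| >= 0.8)\n",
            sum(silac$proteins$call == "up"),
            sum(silac$proteins$call == "down")))
cat(sprintf("global Lys6 incorporation: %.1f%%\n",
            100 * silac$incorporation$global))
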