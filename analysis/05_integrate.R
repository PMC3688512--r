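#!/usr/bin/env Rscript
# Stage 5: cross-layer integration at 90 min.
#
# Pairwise Pearson correlations between transcriptome, translatome and
# proteome, concordance classification (unidirectional vs biased by the
# 0.4 log2 difference rule), translationally-triggered genes and protein
# declines without an RNA change, and the master expressome table.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
res <- run_full(bundle, outdir = "results/tables")

print(res$correlations)
cat(sprintf("translationally triggered: %d genes\n", length(res$triggered)))
cat(sprintf("protein decline without RNA change: %d genes\n",
            length(res$decline)))
cat(sprintf("master table: %d genes x %d columns -> results/tables/master_expressome.tsv\n",
            nrow(res$master), ncol(res$master)))
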