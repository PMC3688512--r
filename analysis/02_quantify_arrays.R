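#!/usr/bin/env Rscript
# Stage 2: two-color array quantification (transcriptome + translatome).
#
# MA computation, within-array LOESS normalization, A-value background
# filtering, replicate combination with a moderated t-statistic, and
# regulation calls for the four hybridizations.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
layers <- quantify_arrays(bundle$arrays, genes = bundle$genome$genes$gene_id)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
for (nm in names(layers))
  write.table(layers[[nm]], file.path("results/tables",
                                      paste0("ratios_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

for (nm in names(layers)) {
  s <- regulation_summary(layers[[nm]]$call)
  cat(sprintf("%-12s quantified %4d | up %3d (%.1f%%) | down %3d (%.1f%%)\n",
              nm, s$quantified, s$up, s$pct_up, s$down, s$pct_down))
}
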