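#!/usr/bin/env Rscript
# Stage 7: proteogenomic discovery of unannotated ORFs.
#
# Builds the six-frame stop-to-stop ORF database, matches the identified
# peptides against it together with the annotated proteome, groups
# sequences sharing peptides, calls groups without an annotated member
# (>= 2 peptides) as potentially novel, and validates the calls against
# strand-specific RNA-seq coverage.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
peptides <- unique(bundle$evidence$peptide[
  bundle$evidence$sample %in% c("reference_mix", "stress_mix")])
genes <- bundle$genome$genes
pg <- discover_novel_orfs(
  bundle$genome$sequence,
  annotated = data.frame(seq_id = genes$gene_id, aa = genes$protein),
  peptides = peptides, track = bundle$coverage)

cat(sprintf("six-frame ORF database: %d entries (>= 7 aa)\n",
            nrow(pg$orf_db)))
cat(sprintf("matched peptides: %d; protein groups: %d\n",
            length(unique(pg$matches$peptide)), nrow(pg$groups)))
calls <- pg$novel_calls
cat(sprintf("novel ORF calls: %d, of which %d RNA-seq supported\n",
            nrow(calls), sum(calls$rnaseq_status == "supported")))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(calls, "results/tables/novel_orf_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
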