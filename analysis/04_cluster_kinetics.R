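#!/usr/bin/env Rscript
# Stage 4: stress-induction kinetics.
#
# Selects genes with significant induction at any time-point, clusters
# the (7, 45, 90 min) profiles by k-means (k = 3, the largest cluster
# subdivided into a/b/c), and computes mean kinetics of the RpoE and
# RpoH2 regulons.

suppressPackageStartupMessages(library(expressome))

bundle <- read_study_bundle("results/bundle")
layers <- quantify_arrays(bundle$arrays, genes = bundle$genome$genes$gene_id)
tc <- build_timecourses(layers)
induced <- select_induced(tc)
cat(sprintf("induced genes (any time-point): %d\n", nrow(induced)))

cl <- kmeans_cluster(induced, k = 3, seed = 1)
sizes <- table(cl$assignments)
big <- names(sizes)[which.max(sizes)]
cl <- subdivide_cluster(cl, big, k2 = 3, seed = 2)
print(table(cl$assignments))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(gene_id = names(cl$assignments),
                       cluster = unname(cl$assignments)),
            "results/tables/cluster_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

genes <- bundle$genome$genes
for (reg in c("RpoE", "RpoH2")) {
  rk <- regulon_kinetics(genes$gene_id[genes$regulon == reg], tc)
  cat(sprintf("%s regulon (n = %d): mean log2 = %.2f / %.2f / %.2f at 7/45/90 min\n",
              reg, rk$n, rk$profile[["t7"]], rk$profile[["t45"]],
              rk$profile[["t90"]]))
}
core <- core_set(tc)
cat(sprintf("core set (up at all three time-points): %d genes\n",
            length(core)))
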