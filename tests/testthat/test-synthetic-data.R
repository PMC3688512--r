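test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 9L)
  b1 <- suppressMessages(run_simulate(cfg))
  b2 <- suppressMessages(run_simulate(cfg))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$scenario, b2$scenario)
  expect_identical(b1$arrays, b2$arrays)
  expect_identical(b1$evidence, b2$evidence)
  expect_identical(b1$coverage, b2$coverage)
})

test_that("genome construction respects the configured layout", {
  cfg <- sim_config(seed = 2L, n_genes = 50L, n_operons = 16L,
                    operon_size_range = c(3L, 3L), n_immediate = 1L,
                    n_rpoe = 1L, n_delayed = 1L, n_rpoh2 = 1L, n_pulse = 0L,
                    n_translational_only = 0L, n_protein_decline = 0L,
                    n_induced_operons = 2L, n_translatome_polarity = 0L,
                    n_novel_orfs = 2L, n_expressed_novel = 1L)
  g <- generate_genome(cfg)
  genes <- g$genes
  expect_equal(nrow(genes), 50L)
  expect_equal(nrow(g$operons), 16L)
  # gene intervals lie within sequence bounds; CDS lengths multiples of 3
  expect_true(all(genes$start >= 1 & genes$end <= nchar(g$sequence)))
  expect_true(all((genes$end - genes$start + 1) %% 3 == 0))
  # operon members are adjacent in genomic order and co-stranded
  ord <- genes[order(genes$start), ]
  for (oid in g$operons$operon_id) {
    idx <- which(ord$operon_id %in% oid)
    expect_equal(idx, seq(min(idx), max(idx)))
    expect_length(unique(ord$strand[idx]), 1L)
  }
  # transcription order: position 1 is the first transcribed gene
  for (oid in g$operons$operon_id) {
    m <- genes[genes$operon_id %in% oid, ]
    first <- m[m$operon_pos == 1L, ]
    if (first$strand == "+") expect_equal(first$start, min(m$start))
    else expect_equal(first$end, max(m$end))
  }
  # planted novel ORFs: >= 7 aa, stop-free, ids disjoint from genes
  nov <- g$novel_orfs
  expect_gte(nrow(nov), 1L)
  expect_true(all(nchar(nov$aa) >= 7L))
  expect_false(any(grepl("*", nov$aa, fixed = TRUE)))
  expect_length(intersect(nov$orf_id, genes$gene_id), 0L)
  # each carries at least two Lys-C peptides of length >= 6
  for (aa in nov$aa)
    expect_gte(length(digest_lysC(aa, max_missed = 0L, min_len = 6L)), 2L)
})

test_that("planted novel ORFs re-translate from their genome coordinates", {
  g <- small_bundle()$genome
  dna <- Biostrings::DNAString(g$sequence)
  for (i in seq_len(nrow(g$novel_orfs))) {
    o <- g$novel_orfs[i, ]
    seg <- Biostrings::subseq(dna, o$start, o$end)
    if (o$strand == "-") seg <- Biostrings::reverseComplement(seg)
    expect_identical(as.character(Biostrings::translate(seg)), o$aa)
  }
  # annotated proteins re-translate too (span includes the stop codon)
  genes <- g$genes[1:10, ]
  for (i in seq_len(nrow(genes))) {
    seg <- Biostrings::subseq(dna, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") seg <- Biostrings::reverseComplement(seg)
    aa <- as.character(Biostrings::translate(seg))
    expect_identical(sub("\\*$", "", aa), genes$protein[i])
  }
})

test_that("planted kinetic classes obey their defining time-courses", {
  b <- small_bundle()
  eff <- b$scenario$effects
  cls <- b$scenario$classes
  imm <- eff[cls$kinetic_class == "immediate", ]
  expect_true(all(imm$t7 >= 0.8 & imm$t45 >= 0.8 & imm$t90 >= 0.8))
  del <- eff[cls$kinetic_class == "delayed", ]
  expect_true(all(del$t7 < 0.8 & del$t45 >= 0.8 & del$t90 >= 0.8))
  pul <- eff[cls$kinetic_class == "pulse", ]
  expect_true(all(pul$t7 >= 0.8 & pul$t45 < 0.8 & pul$t90 < 0.8))
  fl <- eff[cls$kinetic_class == "flat" &
              cls$concordance_class %in% "unchanged", ]
  expect_true(all(fl[, c("t7", "t45", "t90", "poly90", "silac90")] == 0))
  # class counts are assigned exactly, not sampled
  cfg <- small_config()
  expect_equal(sum(cls$kinetic_class == "immediate"), cfg$n_immediate)
  expect_equal(sum(cls$kinetic_class == "delayed"), cfg$n_delayed)
  expect_equal(sum(cls$kinetic_class == "pulse"), cfg$n_pulse)
  expect_equal(sum(cls$concordance_class %in% "translational_only"),
               cfg$n_translational_only)
  expect_equal(sum(cls$concordance_class %in% "protein_decline"),
               cfg$n_protein_decline)
})

test_that("planted operon polarity is a strict staircase in the truth", {
  b <- small_bundle()
  eff <- b$scenario$effects
  genes <- b$genome$genes
  pol <- b$scenario$operon_polarity
  for (i in which(pol$polarity %in% c("5prime", "3prime"))) {
    m <- genes[genes$operon_id %in% pol$operon_id[i], ]
    m <- m[order(m$operon_pos), ]
    v <- eff$t90[match(m$gene_id, eff$gene_id)]
    if (pol$polarity[i] == "5prime") expect_true(all(diff(v) < 0))
    else expect_true(all(diff(v) > 0))
  }
})

test_that("noise-free arrays recover the true effects exactly", {
  b <- noisefree_bundle()
  eff <- b$scenario$effects
  for (lay in c(total_7min = "t7", total_90min = "t90",
                poly_90min = "poly90")) {
    nm <- names(which(c(total_7min = "t7", total_90min = "t90",
                        poly_90min = "poly90") == lay))
    sub <- b$arrays[b$arrays$experiment == nm & b$arrays$replicate == 1, ]
    ma <- compute_ma(sub$cy3, sub$cy5)
    expect_lt(max(abs(ma$M - eff[[lay]][match(sub$gene_id, eff$gene_id)])),
              1e-9)
  }
})

test_that("injected dye bias equals its closed form before normalization", {
  cfg <- small_config(array_noise_sd = 0, dye_bias_amplitude = 0.5,
                      low_expression_fraction = 0)
  b <- suppressMessages(run_simulate(cfg))
  sub <- b$arrays[b$arrays$experiment == "total_90min" &
                    b$arrays$replicate == 1, ]
  ma <- compute_ma(sub$cy3, sub$cy5)
  eff <- b$scenario$effects
  truth <- eff$t90[match(sub$gene_id, eff$gene_id)]
  null_idx <- truth == 0
  base <- b$scenario$baseline[sub$gene_id]
  # noise-free: pre-bias A of a null gene is its baseline
  expected_bias <- 0.5 * sin(base[null_idx] / 2)
  expect_lt(max(abs(ma$M[null_idx] - expected_bias)), 1e-9)
  expect_gt(mean(abs(ma$M[null_idx])), 0.1)
})

test_that("SILAC mixing algebra holds in the noise-free limit", {
  b <- noisefree_bundle()
  ev <- b$evidence
  eff <- b$scenario$effects
  q <- suppressMessages(quantify_silac(ev))
  p <- q$proteins
  i <- match(p$protein_id, eff$gene_id)
  ok <- !is.na(i) & is.finite(p$direct_log2)
  expect_gt(sum(ok), 50L)
  expect_lt(max(abs(p$direct_log2[ok] - eff$silac90[i[ok]])), 1e-12)
  # unchanged protein: H/L identical between mixes
  unchanged <- p$protein_id[ok][abs(eff$silac90[i[ok]]) < 1e-12][1]
  rows <- ev[ev$protein_ids == unchanged & ev$replicate == 1 &
               ev$sample != "heavy_only", ]
  hl <- tapply(ev$intensity_H[ev$protein_ids == unchanged &
                                ev$replicate == 1 &
                                ev$sample != "heavy_only"] /
                 ev$intensity_L[ev$protein_ids == unchanged &
                                  ev$replicate == 1 &
                                  ev$sample != "heavy_only"],
               rows$sample, stats::median)
  expect_equal(unname(hl["reference_mix"]), unname(hl["stress_mix"]))
})

test_that("heavy-only run estimates the configured incorporation", {
  b <- small_bundle()
  inc <- incorporation_rate(b$evidence)
  expect_true(all(inc$per_protein$incorporation >= 0 &
                    inc$per_protein$incorporation <= 1))
  expect_lt(abs(inc$global - 0.96), 0.01)
})

test_that("coverage tracks follow the Poisson expression model", {
  b <- small_bundle()
  g <- b$genome
  cfg <- small_config()
  # expressed planted novel ORF: mean coverage near the configured depth
  nov <- g$novel_orfs[g$novel_orfs$expressed, ][1, ]
  v <- if (nov$strand == "+") b$coverage$plus else b$coverage$minus
  m <- mean(v[nov$start:nov$end])
  expect_lt(abs(m - cfg$coverage_depth) / cfg$coverage_depth, 0.25)
  # strands are independent: a minus-strand gene leaves the plus strand
  # at background level
  mg <- g$genes[g$genes$strand == "-", ][1, ]
  expect_lt(mean(b$coverage$plus[mg$start:mg$end]), 1)
  # zero depth and background give an all-zero track
  cfg0 <- small_config(coverage_depth = 0, coverage_background = 0)
  b0g <- generate_genome(cfg0)
  sc0 <- simulate_true_expression(b0g, cfg0)
  tr0 <- simulate_rnaseq_coverage(sc0, b0g, cfg0)
  expect_true(all(tr0$plus == 0) && all(tr0$minus == 0))
})
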