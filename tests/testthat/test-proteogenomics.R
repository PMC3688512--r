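test_that("six-frame translation emits stop-to-stop ORFs with coordinates", {
  db <- six_frame_translate("ATGAAAGCTGGTTGGACCCTGAAATAA")
  plus1 <- db[db$frame == 1L, ]
  expect_equal(nrow(plus1), 1L)
  expect_equal(plus1$aa, "MKAGWTLK")
  expect_equal(plus1$start, 1L)
  expect_equal(plus1$end, 24L)
  # genomic span is three times the aa length for every ORF
  expect_true(all(db$end - db$start + 1L == 3L * nchar(db$aa)))
  # the length boundary: 6 aa stretches are excluded, 7 aa included
  seq6 <- paste0("TAA", strrep("GCT", 6), "TAA")  # 6 alanines
  expect_equal(nrow(six_frame_translate(seq6)[
    six_frame_translate(seq6)$frame == 1, ]), 0L)
  seq7 <- paste0("TAA", strrep("GCT", 7), "TAA")
  hit <- six_frame_translate(seq7)
  expect_true("AAAAAAA" %in% hit$aa[hit$frame == 1])
  expect_equal(nrow(six_frame_translate("")), 0L)
})

test_that("reverse-complement strand symmetry holds", {
  set.seed(31)
  dna <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  a <- six_frame_translate(dna)
  b <- six_frame_translate(rc)
  # the same peptide set appears, with strands exchanged
  expect_setequal(a$aa, b$aa)
  expect_setequal(a$aa[a$strand == "+"], b$aa[b$strand == "-"])
  # and forward coordinates mirror: start' = L - end + 1
  L <- nchar(dna)
  key_a <- paste(a$aa, L - a$end + 1L, L - a$start + 1L)
  key_b <- paste(b$aa, b$start, b$end)
  expect_setequal(key_a, key_b)
})

test_that("Lys-C digestion enumerates the missed-cleavage lattice", {
  s <- "AAAAAKGGGGGGKCCC"
  d0 <- digest_lysC(s, max_missed = 0)
  expect_setequal(d0, c("AAAAAK", "GGGGGGK"))  # CCC fails min_len
  d1 <- digest_lysC(s, max_missed = 1)
  expect_setequal(d1, c("AAAAAK", "GGGGGGK", "AAAAAKGGGGGGK", "GGGGGGKCCC"))
  d2 <- digest_lysC(s, max_missed = 2)
  expect_setequal(d2, c(d1, "AAAAAKGGGGGGKCCC"))
  # lysine-free sequence: only the whole chain survives
  expect_equal(digest_lysC("MNPQRSTV"), "MNPQRSTV")
  expect_length(digest_lysC("MNP"), 0L)
  # poly-lysine: every window is too short or exceeds max_missed
  expect_length(digest_lysC("KKKKKK"), 0L)
})

test_that("digestion is closed under the missed-cleavage lattice", {
  set.seed(41)
  for (i in 1:10) {
    s <- paste(sample(c("A", "G", "K", "L", "S"), 40, replace = TRUE,
                      prob = c(1, 1, 0.5, 1, 1)), collapse = "")
    got <- digest_lysC(s, max_missed = 2, min_len = 1)
    # independent enumeration from cut positions
    cuts <- c(0, which(strsplit(s, "")[[1]] == "K"), nchar(s))
    cuts <- unique(cuts[cuts <= nchar(s)])
    want <- character(0)
    for (i1 in seq_len(length(cuts) - 1)) {
      for (j in (i1 + 1):length(cuts)) {
        if (j - i1 - 1 > 2) next
        want <- c(want, substr(s, cuts[i1] + 1, cuts[j]))
      }
    }
    expect_identical(sort(got), sort(want))
  }
})

test_that("peptide matching requires Lys-C-consistent termini", {
  db <- data.frame(seq_id = c("p1", "p2"),
                   aa = c("MAAADEKWWWWGK", "TTTTKWWWWGK"),
                   stringsAsFactors = FALSE)
  m <- match_peptides(c("WWWWGK", "MAAADEK", "AAADEK", "WWWWG"), db)
  # shared peptide lists both sequences
  expect_setequal(m$seq_id[m$peptide == "WWWWGK"], c("p1", "p2"))
  # N-terminal peptide matches only where it starts the sequence
  expect_equal(m$seq_id[m$peptide == "MAAADEK"], "p1")
  # internal substring without a K-terminus upstream boundary: no match
  expect_false("AAADEK" %in% m$peptide)
  # truncated peptide (no K end, not at sequence end): no match
  expect_false("WWWWG" %in% m$peptide)
})

test_that("protein grouping separates annotated and novel components", {
  matches <- data.frame(
    peptide = c("AAAAAK", "CCCCCK", "AAAAAK", "DDDDDK", "EEEEEK",
                "FFFFFK"),
    seq_id = c("gene1", "gene1", "orf_over", "orf_new", "orf_new",
               "orf_single"),
    stringsAsFactors = FALSE)
  grp <- group_proteins(matches, annotated_ids = "gene1")
  # the ORF overlapping an annotated gene shares its peptide: not novel
  over <- grp$groups[grepl("orf_over", grp$groups$seq_ids), ]
  expect_true(over$has_annotated_member)
  # unannotated group with two peptides: novel call
  expect_true("orf_new" %in% grp$novel_calls$orf_id)
  # one peptide only: no call
  expect_false("orf_single" %in% grp$novel_calls$orf_id)
  # grouping partitions sequence ids
  all_ids <- unlist(strsplit(grp$groups$seq_ids, ";"))
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("coverage validation applies mean and breadth gates", {
  track <- list(plus = c(rep(50L, 60), rep(0L, 40)),
                minus = rep(0L, 100))
  expect_equal(validate_with_coverage(1, 60, "+", track)$status, "supported")
  expect_equal(validate_with_coverage(1, 100, "+", track)$status,
               "insufficient")  # breadth 0.6 < 0.8
  expect_equal(validate_with_coverage(1, 60, "-", track)$status,
               "insufficient")
  expect_error(validate_with_coverage(50, 120, "+", track), "outside")
})

test_that("planted novel ORFs are discovered and validated end to end", {
  b <- small_bundle()
  res <- run_full(b)
  calls <- res$proteogenomics$novel_calls
  truth <- b$genome$novel_orfs
  key <- function(d) paste(d$start, d$end, d$strand)
  # every planted ORF recovered; no false novels
  expect_setequal(key(calls), key(truth))
  expect_true(all(calls$n_peptides >= 2))
  sup <- calls$rnaseq_status[match(key(truth), key(calls))] == "supported"
  expect_identical(unname(sup), truth$expressed)
  # matched peptides round-trip through the genome coordinates
  dna <- Biostrings::DNAString(b$genome$sequence)
  orf_db <- res$proteogenomics$orf_db
  for (k in seq_len(nrow(calls))) {
    o <- orf_db[orf_db$orf_id == calls$orf_id[k], ]
    seg <- Biostrings::subseq(dna, o$start, o$end)
    if (o$strand == "-") seg <- Biostrings::reverseComplement(seg)
    aa <- as.character(Biostrings::translate(seg))
    peps <- res$proteogenomics$matches$peptide[
      res$proteogenomics$matches$seq_id == o$orf_id]
    expect_true(all(vapply(peps, grepl, NA, x = aa, fixed = TRUE)))
  }
})
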