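#' Write a synthetic study bundle to disk
#'
#' Serializes every artifact of a simulated study in standard plain-text
#' formats: genome FASTA, annotation GFF3 (1-based inclusive coordinates
#' with `operon_id`, `operon_pos` and `regulon` attributes), annotated
#' proteome FASTA, array intensity TSV, peptide evidence TSV, per-strand
#' coverage bedGraph (0-based half-open on disk) and the ground-truth
#' tables.  A manifest with md5 checksums of all files is written last.
#'
#' @param bundle a study bundle as returned by [run_simulate()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_study_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- bundle$genome
  p <- function(f) file.path(dir, f)

  dna <- Biostrings::DNAStringSet(stats::setNames(g$sequence, "chr"))
  Biostrings::writeXStringSet(dna, p("genome.fasta"))
  prot <- Biostrings::AAStringSet(stats::setNames(g$genes$protein,
                                                  g$genes$gene_id))
  Biostrings::writeXStringSet(prot, p("proteins.fasta"))

  gr <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(g$genes$start, g$genes$end),
    strand = g$genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "CDS", phase = 0L, ID = g$genes$gene_id,
    operon_id = g$genes$operon_id,
    operon_pos = g$genes$operon_pos,
    regulon = g$genes$regulon)
  rtracklayer::export(gr, p("annotation.gff3"), format = "gff3")

  tsv <- function(x, f) utils::write.table(
    x, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(bundle$arrays, "arrays.tsv")
  tsv(bundle$evidence, "peptide_evidence.tsv")
  tsv(bundle$scenario$effects, "truth_effects.tsv")
  tsv(bundle$scenario$classes, "truth_classes.tsv")
  tsv(bundle$scenario$operon_polarity, "truth_operon_polarity.tsv")
  tsv(g$novel_orfs, "truth_novel_orfs.tsv")

  write_coverage_bedgraph(bundle$coverage, p("coverage_plus.bedgraph"),
                          p("coverage_minus.bedgraph"))

  files <- c("genome.fasta", "proteins.fasta", "annotation.gff3",
             "arrays.tsv", "peptide_evidence.tsv", "truth_effects.tsv",
             "truth_classes.tsv", "truth_operon_polarity.tsv",
             "truth_novel_orfs.tsv", "coverage_plus.bedgraph",
             "coverage_minus.bedgraph")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  tsv(manifest, "manifest.tsv")
  invisible(manifest)
}

#' Read a study bundle back from disk
#'
#' Counterpart of [write_study_bundle()]; reconstructs the in-memory
#' bundle (genome, truth tables, arrays, evidence and coverage) from the
#' plain-text files.
#'
#' @param dir directory written by [write_study_bundle()].
#' @return a study bundle list.
#' @export
read_study_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  dna <- Biostrings::readDNAStringSet(p("genome.fasta"))
  prot <- Biostrings::readAAStringSet(p("proteins.fasta"))
  gr <- rtracklayer::import(p("annotation.gff3"))
  genes <- data.frame(
    gene_id = gr$ID,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    operon_id = gr$operon_id,
    operon_pos = suppressWarnings(as.integer(gr$operon_pos)),
    regulon = gr$regulon,
    stringsAsFactors = FALSE)
  genes$protein <- as.character(prot)[genes$gene_id]
  tsv <- function(f) utils::read.table(p(f), sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE)
  novel <- tsv("truth_novel_orfs.tsv")
  op_ids <- unique(stats::na.omit(genes$operon_id))
  operons <- data.frame(
    operon_id = op_ids,
    strand = genes$strand[match(op_ids, genes$operon_id)],
    size = as.integer(table(genes$operon_id)[op_ids]),
    stringsAsFactors = FALSE)
  genome <- structure(list(sequence = as.character(dna)[[1]], genes = genes,
                           operons = operons, novel_orfs = novel),
                      class = "synthetic_genome")
  effects <- tsv("truth_effects.tsv")
  classes <- tsv("truth_classes.tsv")
  scenario <- structure(list(effects = effects, classes = classes,
                             operon_polarity = tsv("truth_operon_polarity.tsv")),
                        class = "regulatory_scenario")
  coverage <- read_coverage_bedgraph(p("coverage_plus.bedgraph"),
                                     p("coverage_minus.bedgraph"),
                                     nchar(genome$sequence))
  list(genome = genome, scenario = scenario,
       arrays = tsv("arrays.tsv"), evidence = tsv("peptide_evidence.tsv"),
       coverage = coverage)
}

#' Write per-strand coverage tracks as bedGraph
#'
#' Runs of equal coverage are collapsed to intervals; zero-coverage runs
#' are omitted.  rtracklayer handles the conversion to the 0-based
#' half-open on-disk convention.
#'
#' @param track list with integer vectors `plus`, `minus`.
#' @param path_plus,path_minus output files.
#' @export
write_coverage_bedgraph <- function(track, path_plus, path_minus) {
  one <- function(v, path) {
    r <- S4Vectors::Rle(v)
    ir <- IRanges::successiveIRanges(S4Vectors::runLength(r))
    keep <- S4Vectors::runValue(r) > 0
    gr <- GenomicRanges::GRanges("chr", ir[keep],
                                 score = S4Vectors::runValue(r)[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  one(track$plus, path_plus)
  one(track$minus, path_minus)
  invisible(NULL)
}

#' Read per-strand bedGraph coverage tracks
#'
#' @param path_plus,path_minus bedGraph files.
#' @param genome_length length of the (single) replicon.
#' @return list with integer vectors `plus` and `minus` (1-based
#'   per-nucleotide counts).
#' @export
read_coverage_bedgraph <- function(path_plus, path_minus, genome_length) {
  one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    v <- integer(genome_length)
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    w <- e - s + 1L
    v[sequence(w) + rep(s - 1L, w)] <- rep(as.integer(gr$score), w)
    v
  }
  list(plus = one(path_plus), minus = one(path_minus))
}
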