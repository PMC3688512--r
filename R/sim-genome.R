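#' Generate a synthetic annotated bacterial genome
#'
#' Builds a random genome in which every annotated CDS is assembled from
#' stop-free codons (so its conceptual translation is well defined), genes
#' are organized into co-stranded, adjacent operons plus monocistronic
#' genes, a subset of monocistronic genes carries RpoE / RpoH2 regulon
#' labels, and unannotated ORFs are planted for proteogenomic discovery.
#'
#' Novel ORFs are planted in two ways, mirroring where unannotated genes
#' are found in real bacterial genomes:
#' * intergenic cassettes: a stop-free reading frame flanked by in-frame
#'   stop codons, inserted into an intergenic spacer, guaranteed to yield
#'   at least two Lys-C peptides of length >= 6;
#' * antisense-internal ORFs: naturally occurring stop-free stretches on
#'   the strand opposite to an annotated gene, lying entirely within the
#'   gene's span (discovered by scanning the assembled sequence, so they
#'   are genuine features of the genome rather than insertions).
#'
#' @param config a [sim_config()] object.
#' @return An object of class `synthetic_genome`: a list with elements
#'   `sequence` (character scalar), `genes` (data.frame with `gene_id`,
#'   `start`, `end`, `strand`, `operon_id`, `operon_pos`, `regulon`,
#'   `protein`), `operons` (data.frame with `operon_id`, `strand`, `size`),
#'   and `novel_orfs` (data.frame with `orf_id`, `start`, `end`, `strand`,
#'   `aa`, `type`, `expressed`). Coordinates are 1-based inclusive; gene
#'   spans include the stop codon.
#' @examples
#' g <- generate_genome(sim_config(seed = 2, n_genes = 40, n_operons = 8,
#'                                 operon_size_range = c(3, 3),
#'                                 n_immediate = 2, n_rpoe = 1,
#'                                 n_delayed = 2, n_rpoh2 = 1, n_pulse = 1,
#'                                 n_translational_only = 2,
#'                                 n_protein_decline = 2,
#'                                 n_induced_operons = 3,
#'                                 n_translatome_polarity = 1,
#'                                 n_novel_orfs = 3, n_expressed_novel = 2))
#' nrow(g$genes)
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)

  units <- .plan_units(config)
  n_units <- length(units$size)

  # Novel intergenic cassettes are inserted after randomly chosen units.
  n_internal_target <- min(3L, config$n_novel_orfs)
  n_intergenic <- config$n_novel_orfs - n_internal_target
  cassette_after <- if (n_intergenic > 0L)
    sort(sample.int(n_units, n_intergenic)) else integer(0)

  segs <- list()          # genome pieces in order
  offset <- 0L            # current genome length
  gene_rows <- list()
  novel_rows <- list()
  gi <- 0L

  push <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }

  for (u in seq_len(n_units)) {
    push(.rand_dna(sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)))
    strand <- sample(c("+", "-"), 1L)
    size <- units$size[u]
    # proteins in transcription order
    prot <- vapply(seq_len(size), function(i) .rand_protein(config), "")
    cds <- vapply(prot, .back_translate, "")
    # genome placement order: transcription order on "+", reversed on "-"
    placement <- if (strand == "+") seq_len(size) else rev(seq_len(size))
    for (i in placement) {
      if (i != placement[1]) push(.rand_dna(sample(5:30, 1L)))
      gi <- gi + 1L
      seg <- if (strand == "+") cds[i] else .revcomp(cds[i])
      start <- offset + 1L
      push(seg)
      gene_rows[[gi]] <- data.frame(
        gene_id = NA_character_, start = start, end = offset,
        strand = strand,
        operon_id = if (units$operon[u]) sprintf("op_%04d", u) else NA_character_,
        operon_pos = if (units$operon[u]) i else NA_integer_,
        regulon = "none", protein = prot[i],
        stringsAsFactors = FALSE)
    }
    if (u %in% cassette_after) {
      push(.rand_dna(sample(30:80, 1L)))
      orf <- .make_intergenic_orf(config)
      strand_n <- sample(c("+", "-"), 1L)
      cassette <- paste0("TAA", orf$dna, "TAA")
      if (strand_n == "-") cassette <- .revcomp(cassette)
      start <- offset + 1L
      push(cassette)
      # coordinates of the stop-free stretch (excluding bounding stops)
      if (strand_n == "+") {
        ostart <- start + 3L; oend <- start + 2L + nchar(orf$dna)
      } else {
        ostart <- start + 3L; oend <- start + 2L + nchar(orf$dna)
      }
      novel_rows[[length(novel_rows) + 1L]] <- data.frame(
        orf_id = NA_character_, start = ostart, end = oend,
        strand = strand_n, aa = orf$aa, type = "intergenic",
        stringsAsFactors = FALSE)
      push(.rand_dna(sample(30:80, 1L)))
    }
  }
  push(.rand_dna(sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)))

  sequence <- paste(unlist(segs), collapse = "")
  genes <- do.call(rbind, gene_rows)
  # ids follow genomic order
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$gene_id <- sprintf("RSP_%04d", seq_len(nrow(genes)))
  rownames(genes) <- NULL

  novel <- if (length(novel_rows)) do.call(rbind, novel_rows) else
    data.frame(orf_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), aa = character(0), type = character(0),
               stringsAsFactors = FALSE)

  # antisense-internal novel ORFs found by scanning the assembled genome
  if (n_internal_target > 0L) {
    internal <- .find_internal_orfs(sequence, genes, n_internal_target,
                                    min_aa = 25L)
    if (nrow(internal) < n_internal_target)
      message(sprintf(
        "found %d of %d requested antisense-internal novel ORFs",
        nrow(internal), n_internal_target))
    if (nrow(internal)) novel <- rbind(novel, internal)
  }
  if (nrow(novel)) {
    novel <- novel[order(novel$start), , drop = FALSE]
    novel$orf_id <- sprintf("NORF_%04d", seq_len(nrow(novel)))
    rownames(novel) <- NULL
    expressed_idx <- sample.int(nrow(novel),
                                min(config$n_expressed_novel, nrow(novel)))
    novel$expressed <- seq_len(nrow(novel)) %in% expressed_idx
  } else {
    novel$expressed <- logical(0)
  }

  # regulon labels on monocistronic genes (kinetic classes are assigned on
  # monocistronic genes so operon polarity offsets never interfere)
  mono <- which(is.na(genes$operon_id))
  lab <- sample(mono, config$n_rpoe + config$n_rpoh2)
  genes$regulon[lab[seq_len(config$n_rpoe)]] <- "RpoE"
  genes$regulon[lab[config$n_rpoe + seq_len(config$n_rpoh2)]] <- "RpoH2"

  op_ids <- unique(stats::na.omit(genes$operon_id))
  operons <- data.frame(
    operon_id = op_ids,
    strand = genes$strand[match(op_ids, genes$operon_id)],
    size = as.integer(table(genes$operon_id)[op_ids]),
    stringsAsFactors = FALSE)

  structure(list(sequence = sequence, genes = genes, operons = operons,
                 novel_orfs = novel, seed = config$seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %s nt, %d genes (%d operons), %d planted novel ORFs\n",
              format(nchar(x$sequence), big.mark = ","), nrow(x$genes),
              nrow(x$operons), nrow(x$novel_orfs)))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

.plan_units <- function(config) {
  lo <- config$operon_size_range[1]; hi <- config$operon_size_range[2]
  sizes <- if (config$n_operons > 0L)
    sample(seq.int(lo, hi), config$n_operons, replace = TRUE) else integer(0)
  # shrink greedily if the draw exceeds the gene budget
  while (sum(sizes) > config$n_genes) {
    i <- which.max(sizes)
    if (sizes[i] <= lo) stop("configuration error: operon sizes exceed gene count",
                             call. = FALSE)
    sizes[i] <- sizes[i] - 1L
  }
  n_single <- config$n_genes - sum(sizes)
  size <- c(sizes, rep(1L, n_single))
  operon <- c(rep(TRUE, length(sizes)), rep(FALSE, n_single))
  ord <- sample.int(length(size))
  list(size = size[ord], operon = operon[ord])
}

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
# lysine mildly enriched so Lys-C digestion yields usable peptides
.AA_W <- stats::setNames(rep(1, 20), .AA20); .AA_W["K"] <- 1.3

.rand_protein <- function(config) {
  aa_len <- round(sample(config$gene_length_range[1]:config$gene_length_range[2],
                         1L) / 3)
  paste0("M", paste(sample(.AA20, aa_len - 1L, replace = TRUE,
                           prob = .AA_W), collapse = ""))
}

.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.back_translate <- function(aa) {
  res <- vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- .CODON_TABLE[[a]]
    cods[sample.int(length(cods), 1L)]
  }, "")
  paste0(paste(res, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Intergenic novel ORF with guaranteed Lys-C peptides: lysines at fixed
# interior positions carve the 40-aa product into three pieces of length
# 16, 16 and 8.
.make_intergenic_orf <- function(config) {
  len <- 40L
  aa <- sample(setdiff(.AA20, c("K")), len, replace = TRUE)
  aa[1] <- "M"; aa[16] <- "K"; aa[32] <- "K"
  aa <- paste(aa, collapse = "")
  dna <- .back_translate(aa)
  dna <- substr(dna, 1L, nchar(dna) - 3L)  # stop is added by the cassette
  list(aa = aa, dna = dna)
}

# Scan the assembled genome for stop-free stretches antisense to and fully
# inside a single annotated gene, with at least two Lys-C peptides >= 6 aa.
.find_internal_orfs <- function(sequence, genes, n, min_aa = 25L) {
  orfs <- .six_frame_orfs(sequence, min_aa = min_aa)
  out <- list()
  used_hosts <- character(0)
  for (k in seq_len(nrow(orfs))) {
    if (length(out) >= n) break
    o <- orfs[k, ]
    host <- genes$start <= o$start & genes$end >= o$end &
      genes$strand != o$strand
    if (!any(host)) next
    if (any(genes$gene_id[host] %in% used_hosts)) next
    same <- genes$strand == o$strand & genes$start <= o$end &
      genes$end >= o$start
    if (any(same)) next
    pieces <- digest_lysC(o$aa, max_missed = 0L, min_len = 6L)
    pieces <- pieces[nchar(pieces) <= 35L]  # MS-detectable length range
    if (length(pieces) < 2L) next
    used_hosts <- c(used_hosts, genes$gene_id[host])
    out[[length(out) + 1L]] <- data.frame(
      orf_id = NA_character_, start = o$start, end = o$end,
      strand = o$strand, aa = o$aa, type = "antisense_internal",
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(orf_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), aa = character(0), type = character(0),
               stringsAsFactors = FALSE)
}
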