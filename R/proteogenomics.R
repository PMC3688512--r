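#' Six-frame translation into a stop-to-stop ORF database
#'
#' Conceptually translates a replicon in all six reading frames, splits
#' each frame at stop codons, and keeps every stop-free stretch of at
#' least `min_aa` residues as an ORF.  Identifiers encode the replicon,
#' frame and 1-based amino-acid start position within the frame
#' translation (`<replicon>:<frame>:<aa start>`), so they are
#' deterministic.  Reverse-strand ORF coordinates are mapped back to
#' forward-strand positions; the genomic span excludes the bounding stop
#' codons and equals three times the amino-acid length.  Ambiguity codes
#' translate to `X`.
#'
#' @param dna genome sequence: a character scalar, a
#'   [Biostrings::DNAString] or a named character vector / DNAStringSet
#'   of replicons.
#' @param min_aa minimum ORF length in amino acids.
#' @param replicon replicon name used in identifiers when `dna` is
#'   unnamed.
#' @return data.frame with columns `orf_id`, `replicon`, `frame` (+1..+3,
#'   -1..-3), `start`, `end` (1-based inclusive forward-strand), `strand`,
#'   `aa`.
#' @examples
#' six_frame_translate("ATGAAAGCTGGTTGGACCCTGAAATAA")$aa  # "MKAGWTLK"
#' @export
six_frame_translate <- function(dna, min_aa = 7L, replicon = "chr") {
  if (inherits(dna, "DNAStringSet")) dna <- as.character(dna)
  if (inherits(dna, "DNAString")) dna <- as.character(dna)
  if (is.null(names(dna))) names(dna) <- rep(replicon, length(dna))
  out <- lapply(names(dna), function(nm)
    .six_frame_orfs(dna[[nm]], min_aa = min_aa, replicon = nm))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# core scanner for a single replicon (character scalar)
.six_frame_orfs <- function(sequence, min_aa = 7L, replicon = "chr") {
  L <- nchar(sequence)
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  rows <- list()
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") fwd else rev
      n_cod <- (L - f + 1L) %/% 3L
      if (n_cod < 1L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(subject, f, f + 3L * n_cod - 1L),
        if.fuzzy.codon = "X")))
      # stop-free stretches and their aa start positions in this frame
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      if (!length(parts)) next
      starts <- cumsum(c(1L, nchar(parts[-length(parts)]) + 1L))
      keep <- nchar(parts) >= min_aa
      if (!any(keep)) next
      s_aa <- starts[keep]
      len <- nchar(parts[keep])
      # position on the translated strand
      p1 <- f + 3L * (s_aa - 1L)
      p2 <- f + 3L * (s_aa + len - 1L) - 1L
      if (strand == "+") {
        gstart <- p1; gend <- p2; frame <- f
      } else {
        gstart <- L - p2 + 1L; gend <- L - p1 + 1L; frame <- -f
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = sprintf("%s:%+d:%d", replicon, frame, s_aa),
        replicon = replicon, frame = frame, start = gstart, end = gend,
        strand = strand, aa = parts[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(orf_id = character(0), replicon = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      aa = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$start, res$end), , drop = FALSE]
}

#' In-silico Lys-C digestion
#'
#' Cleaves after every lysine (including K-P bonds, matching Lys-C
#' specificity) and enumerates all peptides spanning at most `max_missed`
#' internal cleavage sites, filtered to a minimum length.  The output is
#' closed under the missed-cleavage lattice: every contiguous run of 1 to
#' `max_missed + 1` fragments appears exactly once.
#'
#' @param sequence protein sequence (character scalar).
#' @param max_missed maximum internal missed cleavages.
#' @param min_len minimum peptide length.
#' @return character vector of peptides (possibly with duplicated strings
#'   when the protein contains sequence repeats).
#' @examples
#' digest_lysC("AAAAAKGGGGGGKCCC", max_missed = 1)
#' @export
digest_lysC <- function(sequence, max_missed = 2L, min_len = 6L) {
  stopifnot(nchar(sequence) > 0L)
  pieces <- strsplit(sequence, "(?<=K)", perl = TRUE)[[1]]
  n <- length(pieces)
  out <- character(0)
  for (miss in 0:max_missed) {
    if (n - miss < 1L) break
    for (i in seq_len(n - miss)) {
      pep <- paste(pieces[i:(i + miss)], collapse = "")
      if (nchar(pep) >= min_len) out <- c(out, pep)
    }
  }
  out
}

# vectorized digestion of many sequences -> data.table(seq_id, peptide)
.digest_table <- function(ids, seqs, max_missed = 2L, min_len = 6L) {
  pieces <- strsplit(seqs, "(?<=K)", perl = TRUE)
  res_id <- vector("list", length(ids))
  res_pep <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    p <- pieces[[k]]
    n <- length(p)
    peps <- character(0)
    nc <- nchar(p)
    for (miss in 0:max_missed) {
      if (n - miss < 1L) break
      i <- seq_len(n - miss)
      # window lengths via cumulative sums
      cs <- cumsum(nc)
      wlen <- cs[i + miss] - c(0, cs)[i]
      sel <- i[wlen >= min_len]
      if (length(sel)) {
        peps <- c(peps, vapply(sel, function(j)
          paste(p[j:(j + miss)], collapse = ""), ""))
      }
    }
    res_pep[[k]] <- peps
    res_id[[k]] <- rep(ids[k], length(peps))
  }
  data.table::data.table(seq_id = unlist(res_id), peptide = unlist(res_pep))
}

#' Match evidence peptides against a sequence database
#'
#' Matches each peptide exactly, requiring Lys-C-consistent termini: the
#' peptide must be preceded by a lysine or the sequence start and must end
#' in a lysine or at the sequence end.  This is implemented by joining
#' against the database's own in-silico Lys-C digest (up to `max_missed`
#' missed cleavages), which enumerates exactly the substrings with such
#' termini.
#'
#' @param peptides character vector of evidence peptide sequences.
#' @param db data.frame with columns `seq_id` and `aa` (six-frame ORFs
#'   and/or annotated proteins).
#' @param max_missed maximum missed cleavages assumed for the evidence.
#' @return data.frame `peptide`, `seq_id` (one row per peptide-sequence
#'   match; peptides matching several sequences yield several rows).
#' @export
match_peptides <- function(peptides, db, max_missed = 2L) {
  dt <- .digest_table(db$seq_id, db$aa, max_missed = max_missed,
                      min_len = min(nchar(peptides)))
  dt <- unique(dt)
  q <- data.table::data.table(peptide = unique(peptides))
  hits <- merge(dt, q, by = "peptide")
  out <- as.data.frame(hits)[, c("peptide", "seq_id")]
  out <- out[order(out$peptide, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group matched sequences into protein groups and call novel ORFs
#'
#' Builds the bipartite peptide-sequence graph from the match table and
#' takes its connected components as protein groups.  Groups containing
#' an annotated member explain their peptides by known genes; groups made
#' up exclusively of unannotated six-frame ORFs and supported by at least
#' `min_peptides` distinct peptides are called potentially novel coding
#' sequences.
#'
#' @param matches a [match_peptides()] table.
#' @param annotated_ids character vector of sequence ids that are
#'   annotated proteins.
#' @param min_peptides minimum distinct peptides for a novel call.
#' @return list with `groups` (data.frame `group_id`, `seq_ids`
#'   (semicolon-joined), `n_peptides`, `has_annotated_member`) and
#'   `novel_calls` (data.frame `orf_id` (member with most peptide
#'   support), `group_id`, `n_peptides`).
#' @export
group_proteins <- function(matches, annotated_ids, min_peptides = 2L) {
  if (!nrow(matches))
    return(list(groups = data.frame(group_id = integer(0),
                                    seq_ids = character(0),
                                    n_peptides = integer(0),
                                    has_annotated_member = logical(0)),
                novel_calls = data.frame(orf_id = character(0),
                                         group_id = integer(0),
                                         n_peptides = integer(0))))
  pep_v <- paste0("pep|", matches$peptide)
  seq_v <- paste0("seq|", matches$seq_id)
  g <- igraph::graph_from_edgelist(cbind(pep_v, seq_v), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  vn <- names(memb)
  rows <- lapply(seq_len(comp$no), function(ci) {
    vs <- vn[memb == ci]
    seqs <- sub("^seq\\|", "", vs[startsWith(vs, "seq|")])
    peps <- sub("^pep\\|", "", vs[startsWith(vs, "pep|")])
    data.frame(group_id = ci,
               seq_ids = paste(sort(seqs), collapse = ";"),
               n_peptides = length(peps),
               has_annotated_member = any(seqs %in% annotated_ids),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)

  novel <- groups[!groups$has_annotated_member &
                    groups$n_peptides >= min_peptides, , drop = FALSE]
  rep_id <- vapply(novel$group_id, function(ci) {
    seqs <- strsplit(groups$seq_ids[groups$group_id == ci], ";")[[1]]
    support <- vapply(seqs, function(s)
      length(unique(matches$peptide[matches$seq_id == s])), 0L)
    seqs[which.max(support)]
  }, "")
  novel_calls <- data.frame(orf_id = rep_id, group_id = novel$group_id,
                            n_peptides = novel$n_peptides,
                            stringsAsFactors = FALSE, row.names = NULL)
  list(groups = groups, novel_calls = novel_calls)
}

#' Validate a novel ORF call against RNA-seq coverage
#'
#' A call is `supported` when the mean per-nucleotide coverage over the
#' ORF on its strand reaches `min_mean` and at least `min_frac` of its
#' positions are covered at all; otherwise `insufficient`.
#'
#' @param start,end,strand ORF coordinates (1-based inclusive, forward
#'   strand coordinates).
#' @param track coverage track: list with integer vectors `plus` and
#'   `minus` (per-nucleotide counts, 1-based).
#' @param min_mean minimum mean coverage.
#' @param min_frac minimum covered fraction.
#' @return list with `status` (`supported` / `insufficient`),
#'   `mean_coverage` and `covered_fraction`.
#' @export
validate_with_coverage <- function(start, end, strand, track,
                                   min_mean = 10, min_frac = 0.8) {
  v <- if (strand == "+") track$plus else track$minus
  if (start < 1L || end > length(v) || start > end)
    stop("ORF lies outside the coverage track", call. = FALSE)
  cov <- v[start:end]
  m <- mean(cov)
  fr <- mean(cov > 0)
  list(status = if (m >= min_mean && fr >= min_frac) "supported"
       else "insufficient",
       mean_coverage = m, covered_fraction = fr)
}

#' Proteogenomic ORF discovery pipeline
#'
#' Builds the six-frame ORF database, combines it with the annotated
#' proteome, matches the evidence peptides, groups proteins, calls novel
#' ORFs and validates them against strand-specific RNA-seq coverage.
#'
#' @param genome_seq genome sequence (character or DNAString).
#' @param annotated data.frame with `seq_id` (gene ids) and `aa`
#'   (annotated protein sequences).
#' @param peptides character vector of identified peptide sequences.
#' @param track coverage track (see [validate_with_coverage()]); optional.
#' @param min_aa minimum ORF length, see [six_frame_translate()].
#' @param min_peptides minimum peptides per novel call.
#' @param max_missed maximum missed cleavages.
#' @param min_mean,min_frac coverage gates.
#' @return list with `orf_db`, `matches`, `groups` and `novel_calls`
#'   (novel calls gain `start`, `end`, `strand`, `rnaseq_status`,
#'   `mean_coverage`, `covered_fraction` when a track is supplied).
#' @export
discover_novel_orfs <- function(genome_seq, annotated, peptides,
                                track = NULL, min_aa = 7L,
                                min_peptides = 2L, max_missed = 2L,
                                min_mean = 10, min_frac = 0.8) {
  orf_db <- six_frame_translate(genome_seq, min_aa = min_aa)
  db <- rbind(data.frame(seq_id = annotated$seq_id, aa = annotated$aa,
                         stringsAsFactors = FALSE),
              data.frame(seq_id = orf_db$orf_id, aa = orf_db$aa,
                         stringsAsFactors = FALSE))
  matches <- match_peptides(unique(peptides), db, max_missed = max_missed)
  grp <- group_proteins(matches, annotated_ids = annotated$seq_id,
                        min_peptides = min_peptides)
  calls <- grp$novel_calls
  i <- match(calls$orf_id, orf_db$orf_id)
  calls$start <- orf_db$start[i]
  calls$end <- orf_db$end[i]
  calls$strand <- orf_db$strand[i]
  if (!is.null(track) && nrow(calls)) {
    val <- lapply(seq_len(nrow(calls)), function(k)
      validate_with_coverage(calls$start[k], calls$end[k], calls$strand[k],
                             track, min_mean = min_mean,
                             min_frac = min_frac))
    calls$rnaseq_status <- vapply(val, `[[`, "", "status")
    calls$mean_coverage <- vapply(val, `[[`, 0, "mean_coverage")
    calls$covered_fraction <- vapply(val, `[[`, 0, "covered_fraction")
  }
  list(orf_db = orf_db, matches = matches, groups = grp$groups,
       novel_calls = calls)
}
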