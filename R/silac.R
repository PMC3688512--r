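#' Heavy/light ratio of one peptide observation
#'
#' @param intensity_H,intensity_L numeric vectors of heavy and light peak
#'   intensities.
#' @return numeric vector `intensity_H / intensity_L`; observations with a
#'   zero (or missing) light intensity are undefined (`NA`) and excluded
#'   downstream.
#' @examples
#' peptide_hl_ratio(c(100, 300, 10), c(100, 100, 0))
#' @export
peptide_hl_ratio <- function(intensity_H, intensity_L) {
  ifelse(!is.na(intensity_L) & intensity_L > 0 & !is.na(intensity_H),
         intensity_H / intensity_L, NA_real_)
}

#' Aggregate peptide ratios to a protein H/L ratio
#'
#' Summarizes the peptide-level heavy/light ratios of one protein in one
#' sample as the median on the log scale (for two peptides this is the
#' geometric mean).  A protein is quantified in a sample only when at
#' least `min_ratio_count` valid peptide ratios support it.
#'
#' @param ratios numeric vector of peptide H/L ratios (NAs are dropped).
#' @param min_ratio_count minimum number of ratio counts for
#'   quantification.
#' @return list with `hl_ratio` (NA when not quantified) and
#'   `ratio_count`.
#' @examples
#' aggregate_protein(c(2, 8))  # geometric mean 4, count 2
#' @export
aggregate_protein <- function(ratios, min_ratio_count = 2L) {
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  n <- length(ratios)
  hl <- if (n >= min_ratio_count) 2^stats::median(log2(ratios)) else NA_real_
  list(hl_ratio = hl, ratio_count = n)
}

#' Direct log2 ratio between two heavy-standard samples
#'
#' With a common heavy standard spiked into both samples, the
#' stress-versus-reference change is the ratio of the two H/L ratios:
#' `log2(hl_reference) - log2(hl_stress)`.  The standard cancels, so a
#' positive value means the protein is more abundant under stress.
#'
#' @param hl_reference,hl_stress numeric H/L ratios (vectors allowed).
#' @return numeric direct log2 ratio; NA when either side is not
#'   quantified.
#' @examples
#' direct_ratio(2, 0.5)  # +2
#' @export
direct_ratio <- function(hl_reference, hl_stress) {
  out <- log2(hl_reference) - log2(hl_stress)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Heavy-label incorporation rate
#'
#' Estimates label incorporation from a heavy-only run as
#' `sum(H) / (sum(H) + sum(L))` per protein; the global estimate is the
#' mean over proteins.
#'
#' @param evidence data.frame with columns `protein_ids`, `sample`,
#'   `intensity_H`, `intensity_L`; rows with `sample == "heavy_only"` are
#'   used.
#' @return list with `global` (mean incorporation fraction) and
#'   `per_protein` (data.frame `protein_id`, `incorporation`).
#' @export
incorporation_rate <- function(evidence) {
  h <- evidence[evidence$sample == "heavy_only", , drop = FALSE]
  if (!nrow(h)) stop("no heavy_only evidence rows", call. = FALSE)
  sh <- tapply(h$intensity_H, h$protein_ids, sum)
  sl <- tapply(h$intensity_L, h$protein_ids, sum)
  frac <- sh / (sh + sl)
  per <- data.frame(protein_id = names(frac),
                    incorporation = unname(frac),
                    stringsAsFactors = FALSE)
  list(global = mean(frac), per_protein = per)
}

#' Significance of replicate direct ratios
#'
#' Per-protein two-sided one-sample t-test of the replicate direct log2
#' ratios against zero, followed by Benjamini-Hochberg step-up adjustment
#' over all tested proteins.  Proteins with fewer than two replicate
#' ratios, or with zero variance across replicates, get an undefined
#' p-value and are called `unchanged` (avoiding spurious certainty).
#' Calls use the same thresholds as the microarray layer: log2 ratio at
#' least 0.8 (or at most -0.8) with adjusted p below `fdr`.
#'
#' @param ratios a named list (or data.frame rows split per protein) of
#'   numeric replicate direct log2 ratios per protein.
#' @param fdr FDR threshold applied to the adjusted p-values.
#' @param up,down log2 ratio thresholds for the calls.
#' @return data.frame with columns `protein_id`, `direct_log2`, `n`,
#'   `p_value`, `p_bh`, `call`.
#' @export
protein_significance <- function(ratios, fdr = 0.05, up = 0.8, down = -0.8) {
  pid <- names(ratios)
  mu <- vapply(ratios, function(v) mean(v, na.rm = TRUE), 0)
  n <- vapply(ratios, function(v) sum(is.finite(v)), 0L)
  p <- vapply(ratios, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L || stats::sd(v) == 0) return(NA_real_)
    tryCatch(stats::t.test(v)$p.value, error = function(e) NA_real_)
  }, 0)
  p_bh <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  p_bh[tested] <- stats::p.adjust(p[tested], method = "BH")
  call <- call_regulated(mu, p_bh, up = up, down = down, alpha = fdr)
  call[is.nan(mu)] <- "not_quantified"
  data.frame(protein_id = pid, direct_log2 = unname(mu), n = unname(n),
             p_value = unname(p), p_bh = unname(p_bh), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Full SILAC quantification pipeline
#'
#' Turns a peptide evidence table into per-protein stress responses:
#' peptide H/L ratios, per-replicate protein H/L ratios (median on the log
#' scale, minimum ratio count), per-replicate direct ratios
#' (reference over stress, so the heavy standard cancels), replicate-level
#' t-tests with Benjamini-Hochberg correction, and regulation calls.
#'
#' @param evidence data.frame with columns `peptide`, `protein_ids`,
#'   `sample`, `replicate`, `intensity_H`, `intensity_L`.
#' @param min_ratio_count minimum peptide ratio count per protein and
#'   sample, see [aggregate_protein()].
#' @param fdr,up,down significance thresholds, see
#'   [protein_significance()].
#' @return list with `proteins` (data.frame `protein_id`, `hl_ref`,
#'   `count_ref`, `hl_stress`, `count_stress`, `direct_log2`, `n`,
#'   `p_value`, `p_bh`, `call`; H/L ratios and counts are means over
#'   replicates), `replicate_ratios` (named list of per-replicate direct
#'   log2 ratios) and `incorporation` (see [incorporation_rate()], NULL
#'   when no heavy-only run is present).
#' @export
quantify_silac <- function(evidence, min_ratio_count = 2L, fdr = 0.05,
                           up = 0.8, down = -0.8) {
  ev <- evidence[evidence$sample %in% c("reference_mix", "stress_mix"), ,
                 drop = FALSE]
  ev$ratio <- peptide_hl_ratio(ev$intensity_H, ev$intensity_L)
  ev <- ev[is.finite(ev$ratio), , drop = FALSE]
  key <- interaction(ev$protein_ids, ev$sample, ev$replicate, drop = TRUE)
  agg <- lapply(split(ev$ratio, key), aggregate_protein,
                min_ratio_count = min_ratio_count)
  info <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  tab <- data.frame(protein_id = info[, 1], sample = info[, 2],
                    replicate = as.integer(info[, 3]),
                    hl = vapply(agg, `[[`, 0, "hl_ratio"),
                    count = vapply(agg, `[[`, 0L, "ratio_count"),
                    stringsAsFactors = FALSE, row.names = NULL)

  proteins <- sort(unique(tab$protein_id))
  reps <- sort(unique(tab$replicate))
  hl_map <- stats::setNames(tab$hl,
                            paste(tab$protein_id, tab$sample, tab$replicate))
  grid <- function(s) paste(rep(proteins, each = length(reps)), s,
                            rep(reps, length(proteins)))
  ref <- unname(hl_map[grid("reference_mix")])
  str <- unname(hl_map[grid("stress_mix")])
  dr <- direct_ratio(ref, str)
  ratio_list <- split(dr, rep(seq_along(proteins), each = length(reps)))
  names(ratio_list) <- proteins
  sig <- protein_significance(ratio_list, fdr = fdr, up = up, down = down)

  mean_or_na <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_
  summ <- function(s, field) {
    v <- tapply(tab[[field]][tab$sample == s],
                tab$protein_id[tab$sample == s], mean_or_na)
    unname(v[proteins])
  }
  prot <- data.frame(protein_id = proteins,
                     hl_ref = summ("reference_mix", "hl"),
                     count_ref = summ("reference_mix", "count"),
                     hl_stress = summ("stress_mix", "hl"),
                     count_stress = summ("stress_mix", "count"),
                     stringsAsFactors = FALSE, row.names = NULL)
  prot <- cbind(prot, sig[match(proteins, sig$protein_id),
                          c("direct_log2", "n", "p_value", "p_bh", "call")])
  prot$call[!is.finite(prot$direct_log2)] <- "not_quantified"
  rownames(prot) <- NULL

  inc <- if (any(evidence$sample == "heavy_only"))
    incorporation_rate(evidence) else NULL
  list(proteins = prot, replicate_ratios = ratio_list, incorporation = inc)
}
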