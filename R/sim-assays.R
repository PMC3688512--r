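#' Simulate two-color microarray intensities
#'
#' Emits per-probe Cy3/Cy5 intensities for the four hybridizations of the
#' study design (total RNA at 7, 45 and 90 min and the polysome fraction
#' at 90 min), each in `config$n_array_replicates` biological replicates.
#' The Cy5 (reference) channel is proportional to the gene's baseline
#' expression; the Cy3 (stress) channel additionally carries the true log2
#' effect.  Both channels receive independent lognormal noise
#' (`config$array_noise_sd` on the log2 scale) and the Cy3 channel an
#' intensity-dependent dye bias `d(A) = amplitude * sin(A/2)` added on the
#' M scale, which is exactly the artifact within-array LOESS normalization
#' must remove.
#'
#' @param scenario a [simulate_true_expression()] result.
#' @param config the matching [sim_config()].
#' @return data.frame with columns `experiment` (`total_7min`,
#'   `total_45min`, `total_90min`, `poly_90min`), `replicate`, `probe_id`,
#'   `gene_id`, `cy3`, `cy5`.
#' @export
simulate_two_color_arrays <- function(scenario, config) {
  stopifnot(inherits(scenario, "regulatory_scenario"))
  set.seed(config$seed + 303L)
  eff <- scenario$effects
  b <- scenario$baseline[eff$gene_id]
  layers <- c(total_7min = "t7", total_45min = "t45",
              total_90min = "t90", poly_90min = "poly90")
  sd <- config$array_noise_sd
  out <- vector("list", length(layers) * config$n_array_replicates)
  k <- 0L
  for (exp_name in names(layers)) {
    e <- eff[[layers[[exp_name]]]]
    for (r in seq_len(config$n_array_replicates)) {
      cy5 <- 2^(b + stats::rnorm(length(b), 0, sd))
      cy3 <- 2^(b + e + stats::rnorm(length(b), 0, sd))
      a0 <- 0.5 * log2(cy3 * cy5)
      cy3 <- cy3 * 2^(config$dye_bias_amplitude * sin(a0 / 2))
      k <- k + 1L
      out[[k]] <- data.frame(
        experiment = exp_name, replicate = r,
        probe_id = paste0("P_", eff$gene_id), gene_id = eff$gene_id,
        cy3 = cy3, cy5 = cy5, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate heavy-standard SILAC peptide evidence
#'
#' For every MS-detectable protein (a configured fraction of the annotated
#' proteome plus all planted novel ORFs), Lys-C peptides (length >= 6, up
#' to one missed cleavage) are sampled from the protein sequence and
#' emitted as heavy/light intensity pairs for the reference and stress
#' mixes in `config$n_silac_replicates` replicate evidence sets, plus a
#' single heavy-only run for incorporation estimation.
#'
#' The mixing model: the heavy channel is proportional to the protein's
#' heavy-standard abundance times the label incorporation probability; the
#' light channel is proportional to the condition abundance (1 for the
#' reference, `2^effect` for the stress sample).  In the noise-free limit
#' the log2 ratio-of-ratios therefore recovers the planted proteome effect
#' exactly, and the standard abundance cancels.  Noise has a protein-level
#' log2 component shared by all peptides of a protein within a run
#' (`protein_factor_sd`) plus independent lognormal peptide-level noise
#' (`peptide_cv`), so protein-level aggregation is meaningfully exercised.
#'
#' Proteins without any Lys-C peptide of length >= 6 are absent from the
#' evidence (a message reports them).
#'
#' @param scenario a [simulate_true_expression()] result.
#' @param genome the matching [generate_genome()] result.
#' @param config the matching [sim_config()].
#' @return data.frame with columns `peptide`, `protein_ids`, `sample`
#'   (`reference_mix`, `stress_mix`, `heavy_only`), `replicate`,
#'   `intensity_H`, `intensity_L`.
#' @export
simulate_silac_evidence <- function(scenario, genome, config) {
  stopifnot(inherits(scenario, "regulatory_scenario"))
  set.seed(config$seed + 404L)
  eff <- scenario$effects
  det <- names(scenario$silac_detected)[scenario$silac_detected]
  prot <- data.frame(
    id = c(det, genome$novel_orfs$orf_id),
    aa = c(genome$genes$protein[match(det, genome$genes$gene_id)],
           genome$novel_orfs$aa),
    effect = c(eff$silac90[match(det, eff$gene_id)],
               rep(0, nrow(genome$novel_orfs))),
    stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + config$peptide_cv^2))
  inc <- config$incorporation
  rows <- vector("list", nrow(prot))
  skipped <- character(0)
  for (i in seq_len(nrow(prot))) {
    peps <- digest_lysC(prot$aa[i], max_missed = 1L, min_len = 6L)
    peps <- unique(peps[nchar(peps) <= 35L])
    if (!length(peps)) { skipped <- c(skipped, prot$id[i]); next }
    if (length(peps) > config$peptides_per_protein)
      peps <- sample(peps, config$peptides_per_protein)
    np <- length(peps)
    S <- 2^stats::rnorm(1, 0, 1)             # heavy-standard abundance
    sub <- vector("list", 2L * config$n_silac_replicates + 1L)
    j <- 0L
    for (r in seq_len(config$n_silac_replicates)) {
      for (smp in c("reference_mix", "stress_mix")) {
        labund <- if (smp == "stress_mix") 2^prot$effect[i] else 1
        f <- 2^stats::rnorm(1, 0, config$protein_factor_sd)
        i0 <- 2^stats::runif(np, 16, 22)
        j <- j + 1L
        sub[[j]] <- data.frame(
          peptide = peps, protein_ids = prot$id[i], sample = smp,
          replicate = r,
          intensity_H = i0 * S * inc * exp(stats::rnorm(np, 0, sdlog)),
          intensity_L = i0 * labund * f * exp(stats::rnorm(np, 0, sdlog)),
          stringsAsFactors = FALSE)
      }
    }
    i0 <- 2^stats::runif(np, 16, 22)
    sub[[j + 1L]] <- data.frame(
      peptide = peps, protein_ids = prot$id[i], sample = "heavy_only",
      replicate = 1L,
      intensity_H = i0 * S * inc * exp(stats::rnorm(np, 0, sdlog)),
      intensity_L = i0 * S * (1 - inc) * exp(stats::rnorm(np, 0, sdlog)),
      stringsAsFactors = FALSE)
    rows[[i]] <- do.call(rbind, sub)
  }
  if (length(skipped))
    message("no Lys-C peptide of length >= 6; absent from evidence: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate strand-specific RNA-seq coverage
#'
#' Per-nucleotide Poisson counts on each genome strand: every annotated
#' gene and every expressed planted novel ORF receives reads at a rate of
#' `config$coverage_depth` scaled by its relative baseline expression
#' (clipped to 1/8 .. 8; novel ORFs at rate `coverage_depth` exactly), on
#' its own strand only, on top of a uniform Poisson background
#' (`coverage_background`) on both strands.
#'
#' @param scenario a [simulate_true_expression()] result.
#' @param genome the matching [generate_genome()] result.
#' @param config the matching [sim_config()].
#' @return list with integer vectors `plus` and `minus` of length
#'   `nchar(genome$sequence)` (per-nucleotide read counts, 1-based).
#' @export
simulate_rnaseq_coverage <- function(scenario, genome, config) {
  stopifnot(inherits(scenario, "regulatory_scenario"))
  set.seed(config$seed + 505L)
  L <- nchar(genome$sequence)
  track <- list(plus = stats::rpois(L, config$coverage_background),
                minus = stats::rpois(L, config$coverage_background))
  b <- scenario$baseline
  rel <- pmin(pmax(2^(b - stats::median(b)), 1 / 8), 8)
  genes <- genome$genes
  for (i in seq_len(nrow(genes))) {
    lambda <- config$coverage_depth * rel[[genes$gene_id[i]]]
    s <- if (genes$strand[i] == "+") "plus" else "minus"
    span <- genes$start[i]:genes$end[i]
    track[[s]][span] <- track[[s]][span] + stats::rpois(length(span), lambda)
  }
  nov <- genome$novel_orfs
  for (i in which(nov$expressed)) {
    s <- if (nov$strand[i] == "+") "plus" else "minus"
    span <- nov$start[i]:nov$end[i]
    track[[s]][span] <- track[[s]][span] +
      stats::rpois(length(span), config$coverage_depth)
  }
  track
}
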