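#' Configuration for a synthetic expressome study
#'
#' Bundles every tunable of the in-silico study generator: genome layout,
#' replicate structure, noise levels, planted regulatory scenario sizes and
#' the labeling/coverage parameters of the proteome and RNA-seq layers.
#' A fixed `seed` makes every generator deterministic (byte-identical
#' outputs on re-runs).
#'
#' The defaults describe the study conditions the package is exercised
#' under: duplicate two-color arrays per condition, quadruplicate SILAC
#' evidence sets, per-channel log2 noise of 0.15, planted effect sizes of
#' 1.5 log2 units, 96% heavy-label incorporation, and a regulatory scenario
#' with immediate (RpoE-like), delayed (RpoH2-like) and pulse kinetic
#' classes, translational-only and protein-decline concordance classes,
#' polar stress-induced operons and unannotated ORFs planted for
#' proteogenomic discovery.
#'
#' @param seed integer; master seed for all generators.
#' @param n_genes number of annotated genes.
#' @param n_operons number of multi-gene operons; remaining genes are
#'   monocistronic.
#' @param operon_size_range integer length-2; inclusive range of operon sizes.
#' @param n_array_replicates biological replicates per array condition.
#' @param n_silac_replicates replicate SILAC evidence sets (digestion x
#'   biological replicates).
#' @param array_noise_sd per-channel log2 intensity noise (lognormal on the
#'   intensity scale).
#' @param dye_bias_amplitude amplitude of the intensity-dependent dye bias
#'   `d(A) = amplitude * sin(A / 2)` added to M before noise-free recovery.
#' @param peptide_cv coefficient of variation of peptide intensities.
#' @param protein_factor_sd log2 sd of the protein-level intensity factor
#'   shared by all peptides of a protein within one run.
#' @param incorporation probability that a peptide molecule of the heavy
#'   standard carries the heavy label; in `[0, 1]`.
#' @param coverage_depth mean RNA-seq per-nucleotide coverage of an
#'   expressed locus at reference expression.
#' @param coverage_background mean background coverage outside expressed loci.
#' @param effect_size planted log2 effect magnitude for regulated genes.
#' @param operon_base_effect log2 effect of the 5'-most (most induced) gene
#'   of a stress-induced polar operon.
#' @param polarity_step per-position log2 decrement (5' polar) or increment
#'   (3' polar) along an induced operon.
#' @param n_immediate,n_rpoe immediately induced genes (up at all three
#'   time-points); `n_rpoe` of them carry the RpoE regulon label.
#' @param n_delayed,n_rpoh2 delayed genes (up from 45 min only); `n_rpoh2`
#'   of them carry the RpoH2 regulon label.
#' @param n_pulse genes induced only at 7 min.
#' @param n_translational_only genes induced in polysomes without a
#'   transcriptome change.
#' @param n_protein_decline genes with protein decline and unchanged RNA.
#' @param n_induced_operons stress-induced multi-gene operons.
#' @param polarity_props named numeric; proportions of induced operons with
#'   5' polarity, 3' polarity, or none (must sum to 1).
#' @param n_translatome_polarity additional operons that are uniformly
#'   induced on the transcriptome but 5'-polar on the translatome.
#' @param n_novel_orfs unannotated ORFs planted for proteogenomic discovery.
#' @param n_expressed_novel how many planted novel ORFs are transcribed
#'   (receive RNA-seq coverage).
#' @param silac_detect_fraction fraction of annotated proteins detected by
#'   the MS layer.
#' @param low_expression_fraction fraction of unregulated genes expressed
#'   below the array background cutoffs.
#' @param gene_length_range inclusive range of CDS lengths in nt (rounded to
#'   codons).
#' @param intergenic_range inclusive range of intergenic spacer lengths in nt.
#' @param peptides_per_protein maximum peptides sampled per protein per
#'   evidence set.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 60, n_operons = 10,
#'                   operon_size_range = c(3, 3))
#' cfg$n_genes
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1500L,
                       n_operons = 150L,
                       operon_size_range = c(4L, 5L),
                       n_array_replicates = 2L,
                       n_silac_replicates = 4L,
                       array_noise_sd = 0.15,
                       dye_bias_amplitude = 0.5,
                       peptide_cv = 0.2,
                       protein_factor_sd = 0.1,
                       incorporation = 0.96,
                       coverage_depth = 50,
                       coverage_background = 0.1,
                       effect_size = 1.5,
                       operon_base_effect = 2.0,
                       polarity_step = 0.5,
                       n_immediate = 18L,
                       n_rpoe = 12L,
                       n_delayed = 42L,
                       n_rpoh2 = 42L,
                       n_pulse = 10L,
                       n_translational_only = 18L,
                       n_protein_decline = 15L,
                       n_induced_operons = 20L,
                       polarity_props = c(`5prime` = 0.7, `3prime` = 0.2,
                                          none = 0.1),
                       n_translatome_polarity = 4L,
                       n_novel_orfs = 19L,
                       n_expressed_novel = 13L,
                       silac_detect_fraction = 0.8,
                       low_expression_fraction = 0.1,
                       gene_length_range = c(300L, 900L),
                       intergenic_range = c(60L, 300L),
                       peptides_per_protein = 8L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_operons = as.integer(n_operons),
    operon_size_range = as.integer(operon_size_range),
    n_array_replicates = as.integer(n_array_replicates),
    n_silac_replicates = as.integer(n_silac_replicates),
    array_noise_sd = array_noise_sd,
    dye_bias_amplitude = dye_bias_amplitude,
    peptide_cv = peptide_cv,
    protein_factor_sd = protein_factor_sd,
    incorporation = incorporation,
    coverage_depth = coverage_depth,
    coverage_background = coverage_background,
    effect_size = effect_size,
    operon_base_effect = operon_base_effect,
    polarity_step = polarity_step,
    n_immediate = as.integer(n_immediate),
    n_rpoe = as.integer(n_rpoe),
    n_delayed = as.integer(n_delayed),
    n_rpoh2 = as.integer(n_rpoh2),
    n_pulse = as.integer(n_pulse),
    n_translational_only = as.integer(n_translational_only),
    n_protein_decline = as.integer(n_protein_decline),
    n_induced_operons = as.integer(n_induced_operons),
    polarity_props = polarity_props,
    n_translatome_polarity = as.integer(n_translatome_polarity),
    n_novel_orfs = as.integer(n_novel_orfs),
    n_expressed_novel = as.integer(n_expressed_novel),
    silac_detect_fraction = silac_detect_fraction,
    low_expression_fraction = low_expression_fraction,
    gene_length_range = as.integer(gene_length_range),
    intergenic_range = as.integer(intergenic_range),
    peptides_per_protein = as.integer(peptides_per_protein)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic expressome study configuration\n")
  cat(sprintf("  seed %d; %d genes, %d operons (size %d-%d)\n",
              x$seed, x$n_genes, x$n_operons,
              x$operon_size_range[1], x$operon_size_range[2]))
  cat(sprintf("  arrays: %d replicates, noise sd %.3g, dye bias %.3g\n",
              x$n_array_replicates, x$array_noise_sd, x$dye_bias_amplitude))
  cat(sprintf("  SILAC: %d replicates, peptide CV %.3g, incorporation %.3g\n",
              x$n_silac_replicates, x$peptide_cv, x$incorporation))
  cat(sprintf("  planted: %d immediate / %d delayed / %d pulse, %d trans-only, %d protein-decline\n",
              x$n_immediate, x$n_delayed, x$n_pulse,
              x$n_translational_only, x$n_protein_decline))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L)
    stop("configuration error: n_genes must be >= 1", call. = FALSE)
  if (length(cfg$operon_size_range) != 2L ||
      any(cfg$operon_size_range < 1L) ||
      cfg$operon_size_range[1] > cfg$operon_size_range[2])
    stop("configuration error: invalid operon_size_range", call. = FALSE)
  if (cfg$n_operons * cfg$operon_size_range[1] > cfg$n_genes)
    stop("configuration error: operon sizes exceed gene count", call. = FALSE)
  for (f in c("array_noise_sd", "peptide_cv", "protein_factor_sd",
              "coverage_depth", "coverage_background"))
    if (cfg[[f]] < 0)
      stop(sprintf("configuration error: %s must be >= 0", f), call. = FALSE)
  if (cfg$incorporation < 0 || cfg$incorporation > 1)
    stop("configuration error: incorporation must lie in [0, 1]",
         call. = FALSE)
  if (abs(sum(cfg$polarity_props) - 1) > 1e-8)
    stop("configuration error: polarity_props must sum to 1", call. = FALSE)
  if (cfg$n_expressed_novel > cfg$n_novel_orfs)
    stop("configuration error: n_expressed_novel exceeds n_novel_orfs",
         call. = FALSE)
  n_singletons <- cfg$n_genes - .operon_gene_budget(cfg)
  n_planted <- cfg$n_immediate + cfg$n_delayed + cfg$n_pulse +
    cfg$n_translational_only + cfg$n_protein_decline
  if (n_planted > n_singletons)
    stop(sprintf(paste0("configuration error: %d planted single-gene classes",
                        " but only ~%d monocistronic genes available"),
                 n_planted, n_singletons), call. = FALSE)
  if (cfg$n_rpoe > cfg$n_immediate || cfg$n_rpoh2 > cfg$n_delayed)
    stop("configuration error: regulon sizes exceed their kinetic classes",
         call. = FALSE)
  invisible(cfg)
}

# Upper bound on the number of genes consumed by operons (used for
# validating that enough monocistronic genes remain for planted classes).
.operon_gene_budget <- function(cfg) {
  cfg$n_operons * cfg$operon_size_range[2]
}
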