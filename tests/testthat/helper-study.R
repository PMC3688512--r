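# Shared study fixtures, generated in code and cached per test session.

.study_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small study: 200 genes with planted classes scaled down proportionally.
small_config <- function(seed = 5L, ...) {
  sim_config(seed = seed, n_genes = 200L, n_operons = 20L,
             n_immediate = 6L, n_rpoe = 3L, n_delayed = 8L, n_rpoh2 = 4L,
             n_pulse = 3L, n_translational_only = 5L, n_protein_decline = 4L,
             n_induced_operons = 5L, n_translatome_polarity = 2L,
             n_novel_orfs = 6L, n_expressed_novel = 4L, ...)
}

small_bundle <- function() {
  if (is.null(.study_cache$small))
    .study_cache$small <- suppressMessages(run_simulate(small_config()))
  .study_cache$small
}

# Same layout with all noise switched off (self-consistency checks).
noisefree_bundle <- function() {
  if (is.null(.study_cache$noisefree))
    .study_cache$noisefree <- suppressMessages(run_simulate(
      small_config(array_noise_sd = 0, dye_bias_amplitude = 0,
                   peptide_cv = 0, protein_factor_sd = 0,
                   low_expression_fraction = 0)))
  .study_cache$noisefree
}

# The full default study plus pipeline results and recovery metrics
# (computed once; used by the end-to-end acceptance checks).
default_run <- function() {
  if (is.null(.study_cache$default)) {
    t0 <- Sys.time()
    bundle <- suppressMessages(run_simulate(sim_config(seed = 1L)))
    results <- suppressWarnings(run_full(bundle))
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .study_cache$default <- list(
      bundle = bundle, results = results,
      metrics = evaluate_against_truth(results, bundle),
      elapsed_sec = elapsed)
  }
  .study_cache$default
}

# Adjusted Rand index against a reference partition (used for the
# separability checks of the clustering stage).
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Vectors with an exact prescribed Pearson correlation.
make_correlated <- function(r, n = 200L, seed = 11L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  x <- as.numeric(scale(x)); z <- as.numeric(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
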