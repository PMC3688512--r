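#' Plant the true regulatory scenario on a synthetic genome
#'
#' Assigns every annotated gene a kinetic class, a cross-layer concordance
#' class, a baseline expression level and true log2 effects in all five
#' measured layers (transcriptome at 7, 45 and 90 min; translatome and
#' proteome at 90 min).  Stress-induced operons additionally receive a
#' polarity class whose per-position offsets are applied on top of the
#' member genes' effects.
#'
#' Kinetic classes and their true transcriptome effects (with
#' `E = config$effect_size`):
#' * `immediate` (contains the RpoE-labeled genes): `E` at 7, 45 and 90 min;
#' * `delayed` (contains the RpoH2-labeled genes): 0.3 at 7 min, `E` later;
#' * `pulse`: `E` at 7 min only, 0.2 afterwards;
#' * `flat`: 0 throughout.
#'
#' Concordance classes at 90 min: `unidirectional` genes carry the same
#' effect in all layers; `translational_only` genes are induced in
#' polysomes with unchanged total mRNA and protein; `protein_decline`
#' genes lose protein with unchanged RNA; everything else is `unchanged`.
#' Genes inside induced operons carry `NA` here, as their pairwise
#' concordance follows from the polarity offsets.
#'
#' @param genome a [generate_genome()] result.
#' @param config the [sim_config()] used to generate `genome`.
#' @return An object of class `regulatory_scenario`: list with `effects`
#'   (data.frame `gene_id`, `t7`, `t45`, `t90`, `poly90`, `silac90`),
#'   `classes` (data.frame `gene_id`, `kinetic_class`, `concordance_class`),
#'   `baseline` (named log2 expression levels), `silac_detected` (named
#'   logical), and `operon_polarity` (data.frame `operon_id`, `polarity`,
#'   `translatome_only`).
#' @export
simulate_true_expression <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  set.seed(config$seed + 202L)
  genes <- genome$genes
  n <- nrow(genes)
  ids <- genes$gene_id
  E <- config$effect_size

  kinetic <- rep("flat", n)
  concord <- rep("unchanged", n)
  mono <- which(is.na(genes$operon_id))

  rpoe_idx <- which(genes$regulon == "RpoE")
  rpoh2_idx <- which(genes$regulon == "RpoH2")
  pool <- setdiff(mono, c(rpoe_idx, rpoh2_idx))

  take <- function(k) {
    stopifnot(k <= length(pool))
    out <- if (k > 0L) sample(pool, k) else integer(0)
    pool <<- setdiff(pool, out)
    out
  }
  immediate <- c(rpoe_idx, take(config$n_immediate - config$n_rpoe))
  delayed <- c(rpoh2_idx, take(config$n_delayed - config$n_rpoh2))
  pulse <- take(config$n_pulse)
  trans_only <- take(config$n_translational_only)
  prot_decline <- take(config$n_protein_decline)

  kinetic[immediate] <- "immediate"
  kinetic[delayed] <- "delayed"
  kinetic[pulse] <- "pulse"
  concord[c(immediate, delayed)] <- "unidirectional"
  concord[trans_only] <- "translational_only"
  concord[prot_decline] <- "protein_decline"

  eff <- matrix(0, n, 5,
                dimnames = list(ids, c("t7", "t45", "t90", "poly90", "silac90")))
  eff[immediate, ] <- matrix(rep(c(E, E, E, E, E), each = length(immediate)),
                             ncol = 5)
  eff[delayed, ] <- matrix(rep(c(0.3, E, E, E, E), each = length(delayed)),
                           ncol = 5)
  eff[pulse, ] <- matrix(rep(c(E, 0.2, 0.2, 0.2, 0.2), each = length(pulse)),
                         ncol = 5)
  eff[trans_only, "poly90"] <- E
  eff[prot_decline, "silac90"] <- -E

  # --- operon induction and polarity ---------------------------------------
  ops <- genome$operons
  polarity <- data.frame(operon_id = ops$operon_id,
                         polarity = rep("not_induced", nrow(ops)),
                         translatome_only = rep(FALSE, nrow(ops)),
                         stringsAsFactors = FALSE)
  n_ind <- min(config$n_induced_operons, nrow(ops))
  n_tp <- min(config$n_translatome_polarity, nrow(ops) - n_ind)
  picked <- if (nrow(ops)) sample.int(nrow(ops), n_ind + n_tp) else integer(0)
  ind_ops <- picked[seq_len(n_ind)]
  tp_ops <- picked[n_ind + seq_len(n_tp)]

  # exact class counts from the configured proportions
  cls_names <- c("5prime", "3prime", "none")
  counts <- floor(config$polarity_props[cls_names] * n_ind)
  rem <- n_ind - sum(counts)
  if (rem > 0) {
    frac <- config$polarity_props[cls_names] * n_ind - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  op_class <- rep(cls_names, counts)

  B <- config$operon_base_effect
  step <- config$polarity_step
  staircase <- function(k, cls) {
    switch(cls,
           "5prime" = B - (seq_len(k) - 1L) * step,
           "3prime" = B - (k - seq_len(k)) * step,
           "none" = rep(B, k))
  }
  for (j in seq_along(ind_ops)) {
    oid <- ops$operon_id[ind_ops[j]]
    cls <- op_class[j]
    polarity$polarity[polarity$operon_id == oid] <- cls
    members <- which(genes$operon_id %in% oid)
    members <- members[order(genes$operon_pos[members])]
    v <- staircase(length(members), cls)
    eff[members, c("t45", "t90", "poly90", "silac90")] <-
      matrix(rep(v, 4L), ncol = 4L)
    concord[members] <- NA_character_
  }
  for (oi in tp_ops) {
    oid <- ops$operon_id[oi]
    polarity$polarity[polarity$operon_id == oid] <- "none"
    polarity$translatome_only[polarity$operon_id == oid] <- TRUE
    members <- which(genes$operon_id %in% oid)
    members <- members[order(genes$operon_pos[members])]
    eff[members, c("t45", "t90", "silac90")] <- B
    eff[members, "poly90"] <- staircase(length(members), "5prime")
    concord[members] <- NA_character_
  }

  # --- baselines and MS detectability ---------------------------------------
  planted <- kinetic != "flat" | !concord %in% "unchanged" |
    genes$regulon != "none" | is.na(concord)
  baseline <- numeric(n)
  baseline[planted] <- stats::runif(sum(planted), 11.5, 13.5)
  idle <- which(!planted)
  low <- idle[stats::runif(length(idle)) < config$low_expression_fraction]
  hi <- setdiff(idle, low)
  baseline[low] <- stats::runif(length(low), 8, 9.5)
  baseline[hi] <- stats::runif(length(hi), 11, 14)
  names(baseline) <- ids

  silac_detected <- stats::setNames(
    stats::runif(n) < config$silac_detect_fraction, ids)

  structure(list(
    effects = data.frame(gene_id = ids, eff, row.names = NULL,
                         stringsAsFactors = FALSE),
    classes = data.frame(gene_id = ids, kinetic_class = kinetic,
                         concordance_class = concord, row.names = NULL,
                         stringsAsFactors = FALSE),
    baseline = baseline,
    silac_detected = silac_detected,
    operon_polarity = polarity,
    seed = config$seed), class = "regulatory_scenario")
}

#' @export
print.regulatory_scenario <- function(x, ...) {
  cat(sprintf("Regulatory scenario for %d genes\n", nrow(x$effects)))
  print(table(x$classes$kinetic_class))
  invisible(x)
}
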