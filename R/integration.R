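#' Pearson correlation between two expression layers
#'
#' Computes the Pearson correlation of log2 ratios over the genes
#' quantified in both layers, together with the squared correlation (the
#' share of variance in one layer explainable by the other).
#'
#' @param a,b data.frames with columns `gene_id` and `log2_ratio` (NAs are
#'   treated as not quantified).
#' @return list with `n` (shared quantified genes), `r` and `r_squared`
#'   (unrounded; round to two decimals for reporting).
#' @export
correlate_layers <- function(a, b) {
  i <- match(b$gene_id, a$gene_id)
  x <- a$log2_ratio[i]
  y <- b$log2_ratio
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L)
    stop("fewer than 3 genes quantified in both layers", call. = FALSE)
  r <- stats::cor(x[ok], y[ok])
  list(n = sum(ok), r = r, r_squared = r^2)
}

#' Classify cross-layer concordance of regulated genes
#'
#' A gene enters classification when it is regulated (|log2| >= `reg` with
#' p < `alpha`) in at least one of the two layers; regulated genes are
#' `unidirectional` when the absolute log2 ratio difference between the
#' layers is below `diff`, and `biased` otherwise.  Genes below the
#' regulation threshold in both layers are `unchanged`; genes quantified
#' in only one layer carry `NA`.
#'
#' @param a,b data.frames with columns `gene_id`, `log2_ratio`, `p_value`
#'   (the proteome layer may supply adjusted p-values).
#' @param reg regulation threshold on |log2|.
#' @param diff log2 difference separating unidirectional from biased.
#' @param alpha p-value gate for the regulation test.
#' @return data.frame `gene_id`, `log2_A`, `log2_B`, `regulated_in`
#'   (`A`, `B`, `both`, `neither`), `class`.
#' @export
classify_concordance <- function(a, b, reg = 0.8, diff = 0.4, alpha = 0.05) {
  ids <- union(a$gene_id, b$gene_id)
  la <- a$log2_ratio[match(ids, a$gene_id)]
  pa <- a$p_value[match(ids, a$gene_id)]
  lb <- b$log2_ratio[match(ids, b$gene_id)]
  pb <- b$p_value[match(ids, b$gene_id)]
  reg_a <- !is.na(la) & !is.na(pa) & abs(la) >= reg & pa < alpha
  reg_b <- !is.na(lb) & !is.na(pb) & abs(lb) >= reg & pb < alpha
  regulated_in <- ifelse(reg_a & reg_b, "both",
                         ifelse(reg_a, "A", ifelse(reg_b, "B", "neither")))
  cls <- rep(NA_character_, length(ids))
  both_q <- is.finite(la) & is.finite(lb)
  cls[both_q & regulated_in == "neither"] <- "unchanged"
  hit <- both_q & regulated_in != "neither"
  cls[hit] <- ifelse(abs(la[hit] - lb[hit]) < diff, "unidirectional",
                     "biased")
  data.frame(gene_id = ids, log2_A = la, log2_B = lb,
             regulated_in = regulated_in, class = cls,
             stringsAsFactors = FALSE)
}

#' Translationally triggered genes
#'
#' Genes significantly induced in the polysome fraction whose
#' transcriptome induction lags by at least `diff` log2 units.
#'
#' @param transcriptome,translatome layer tables (`gene_id`,
#'   `log2_ratio`, `p_value`).
#' @param up,alpha induction thresholds on the translatome.
#' @param diff minimum (translatome - transcriptome) log2 difference.
#' @return character vector of gene ids.
#' @export
translationally_triggered <- function(transcriptome, translatome, up = 0.8,
                                      alpha = 0.05, diff = 0.4) {
  ids <- translatome$gene_id
  lt <- translatome$log2_ratio
  pt_ <- translatome$p_value
  lx <- transcriptome$log2_ratio[match(ids, transcriptome$gene_id)]
  hit <- !is.na(lt) & !is.na(pt_) & lt >= up & pt_ < alpha &
    !is.na(lx) & (lt - lx) >= diff
  ids[hit]
}

#' Protein decline without matching RNA change
#'
#' Proteins with a significant abundance decline whose RNA layer does not
#' drop to the same extent (signed difference of at least `diff`).
#'
#' @param proteome table with `gene_id`, `log2_ratio` and `p_value`
#'   (adjusted p-values).
#' @param rna_layer transcriptome or translatome table.
#' @param down,alpha decline thresholds on the proteome.
#' @param diff minimum (RNA - protein) log2 difference.
#' @return character vector of gene ids.
#' @export
protein_decline_without_rna_change <- function(proteome, rna_layer,
                                               down = -0.8, alpha = 0.05,
                                               diff = 0.4) {
  ids <- proteome$gene_id
  lp <- proteome$log2_ratio
  pp <- proteome$p_value
  lr <- rna_layer$log2_ratio[match(ids, rna_layer$gene_id)]
  hit <- !is.na(lp) & !is.na(pp) & lp <= down & pp < alpha &
    !is.na(lr) & (lr - lp) >= diff
  ids[hit]
}

#' Integrate all layers into a master expressome table
#'
#' One row per gene over the union of quantified genes across layers, with
#' every layer's log2 ratio, p-value and call, cross-layer concordance
#' classes, cluster labels and operon/regulon annotations.  Genes missing
#' from a layer carry explicit `NA`s.
#'
#' @param layers named list of layer tables (`gene_id`, `log2_ratio`,
#'   `p_value`, `call`); typical names are `total_7min`, `total_45min`,
#'   `total_90min`, `poly_90min`, `silac_90min`.
#' @param annotations optional data.frame keyed by `gene_id` (e.g. operon
#'   and regulon columns from the genome annotation).
#' @param clusters optional named vector of cluster labels per gene.
#' @param reg,diff,alpha concordance thresholds, see
#'   [classify_concordance()].
#' @return data.frame, one row per gene.
#' @export
integrate_expressome <- function(layers, annotations = NULL, clusters = NULL,
                                 reg = 0.8, diff = 0.4, alpha = 0.05) {
  for (nm in names(layers))
    if (anyDuplicated(layers[[nm]]$gene_id))
      stop("duplicate gene_id in layer ", nm, call. = FALSE)
  ids <- sort(Reduce(union, lapply(layers, function(t)
    t$gene_id[!is.na(t$log2_ratio)])))
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (nm in names(layers)) {
    t <- layers[[nm]]
    i <- match(ids, t$gene_id)
    out[[paste0(nm, "_log2")]] <- t$log2_ratio[i]
    out[[paste0(nm, "_p")]] <- t$p_value[i]
    out[[paste0(nm, "_call")]] <- t$call[i]
  }
  pairs <- list(c("total_90min", "poly_90min"),
                c("total_90min", "silac_90min"),
                c("poly_90min", "silac_90min"))
  for (pr in pairs) {
    if (!all(pr %in% names(layers))) next
    cc <- classify_concordance(layers[[pr[1]]], layers[[pr[2]]],
                               reg = reg, diff = diff, alpha = alpha)
    out[[paste0("concordance_", pr[1], "_vs_", pr[2])]] <-
      cc$class[match(ids, cc$gene_id)]
  }
  if (!is.null(clusters))
    out$cluster <- unname(clusters[ids])
  if (!is.null(annotations)) {
    i <- match(ids, annotations$gene_id)
    for (nm in setdiff(names(annotations), "gene_id"))
      out[[nm]] <- annotations[[nm]][i]
  }
  out
}
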