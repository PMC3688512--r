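#' Call expression polarity of one operon
#'
#' Operon polarity is the systematic decrease (5' polarity) or increase
#' (3' polarity) of expression change along the gene order of a
#' polycistronic operon.  The call combines a rank trend with a magnitude
#' gate: the trend statistic is the Spearman correlation between gene
#' position (1..k, 5' first) and the per-gene values; `5prime` requires a
#' trend of at most -0.5 together with a first-minus-last difference of at
#' least `epsilon`, `3prime` the mirror image, anything else is `none`.
#' For two-gene operons the trend is +-1 by construction, so the epsilon
#' gate alone decides.
#'
#' @param values numeric per-gene values in transcription order (log2
#'   ratios or log2 expression levels); `NA` members are dropped (order
#'   preserved).
#' @param epsilon minimum end-to-end log2 difference.
#' @return list with `call` (`5prime`, `3prime`, `none`, or `NA` when
#'   fewer than two members are quantified), `trend` (Spearman rho),
#'   `strength` (first minus last value) and `n` used.
#' @examples
#' call_polarity(c(1.5, 1.0, 0.5))$call  # "5prime"
#' @export
call_polarity <- function(values, epsilon = 0.1) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2L)
    return(list(call = NA_character_, trend = NA_real_,
                strength = NA_real_, n = n))
  rho <- suppressWarnings(stats::cor(seq_len(n), v, method = "spearman"))
  if (is.na(rho)) rho <- 0  # ties everywhere: no trend
  strength <- v[1] - v[n]
  call <- "none"
  if (rho <= -0.5 && strength >= epsilon) call <- "5prime"
  if (rho >= 0.5 && -strength >= epsilon) call <- "3prime"
  list(call = call, trend = rho, strength = strength, n = n)
}

#' Polarity strength of an operon
#'
#' First-gene value minus last-gene value; positive values mean 5'
#' polarity.  Units follow the input (log2 ratios or log2 levels).
#'
#' @param values numeric per-gene values in transcription order.
#' @return numeric scalar (NA when fewer than two quantified members).
#' @export
polarity_strength <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  v[1] - v[length(v)]
}

#' Compare operon polarity before and after stress
#'
#' Computes polarity strengths from per-gene log2 expression levels (not
#' ratios) at two time-points and their difference; genes missing at
#' either time-point are excluded pairwise.  A positive `delta` means
#' polarity was induced by the stress.
#'
#' @param levels_0,levels_90 numeric per-gene log2 expression levels in
#'   transcription order.
#' @return list with `strength_0`, `strength_90` and `delta`
#'   (`strength_90 - strength_0`).
#' @export
compare_prepost_polarity <- function(levels_0, levels_90) {
  stopifnot(length(levels_0) == length(levels_90))
  ok <- !is.na(levels_0) & !is.na(levels_90)
  s0 <- polarity_strength(levels_0[ok])
  s90 <- polarity_strength(levels_90[ok])
  list(strength_0 = s0, strength_90 = s90, delta = s90 - s0)
}

#' Cross-layer concordance of polarity calls
#'
#' Reports pairwise agreement of per-layer polarity calls for one operon
#' and flags translatome-only polarity (no transcriptome polarity but a
#' polar translatome), the pattern where translation alone imposes the
#' positional gradient.
#'
#' @param calls named character vector of per-layer calls (names such as
#'   `total_90min`, `poly_90min`, `silac_90min`; values `5prime`,
#'   `3prime`, `none` or `NA`).
#' @return list with `agreement` (data.frame of layer pairs with
#'   `agree`), and `translatome_only` (logical).
#' @export
polarity_concordance_across_layers <- function(calls) {
  layers <- names(calls)
  prs <- if (length(layers) >= 2L) utils::combn(layers, 2L) else
    matrix(character(0), nrow = 2)
  agreement <- data.frame(
    layer_a = prs[1, ], layer_b = prs[2, ],
    agree = vapply(seq_len(ncol(prs)), function(j) {
      a <- calls[[prs[1, j]]]; b <- calls[[prs[2, j]]]
      if (is.na(a) || is.na(b)) NA else a == b
    }, NA),
    stringsAsFactors = FALSE)
  trans <- calls[["total_90min"]]
  poly <- calls[["poly_90min"]]
  translatome_only <- !is.null(trans) && !is.null(poly) &&
    !is.na(trans) && !is.na(poly) &&
    trans == "none" && poly %in% c("5prime", "3prime")
  list(agreement = agreement, translatome_only = translatome_only)
}

#' Polarity calls for all operons on one layer
#'
#' Applies [call_polarity()] to every operon using the layer's per-gene
#' log2 ratios, restricted to operons considered stress-induced on that
#' layer (at least one member called `up`), since polarity of an
#' uninduced operon's ratios carries no signal.
#'
#' @param operons data.frame with columns `operon_id` and ordered
#'   membership given through `genes` (see below).
#' @param genes data.frame with columns `gene_id`, `operon_id`,
#'   `operon_pos` (transcription order).
#' @param layer layer table (`gene_id`, `log2_ratio`, `call`).
#' @param epsilon magnitude gate, see [call_polarity()].
#' @param induced_only if `TRUE` (default) only operons with an `up`
#'   member are called; otherwise all operons.
#' @return data.frame `operon_id`, `call`, `trend`, `strength`,
#'   `n_quantified`, `induced`.
#' @export
call_polarity_all <- function(operons, genes, layer, epsilon = 0.1,
                              induced_only = TRUE) {
  rows <- lapply(operons$operon_id, function(oid) {
    members <- genes[genes$operon_id %in% oid, , drop = FALSE]
    members <- members[order(members$operon_pos), , drop = FALSE]
    i <- match(members$gene_id, layer$gene_id)
    vals <- layer$log2_ratio[i]
    induced <- any(layer$call[i] == "up", na.rm = TRUE)
    if (induced_only && !induced)
      return(data.frame(operon_id = oid, call = NA_character_,
                        trend = NA_real_, strength = NA_real_,
                        n_quantified = sum(!is.na(vals)), induced = induced,
                        stringsAsFactors = FALSE))
    pc <- call_polarity(vals, epsilon = epsilon)
    data.frame(operon_id = oid, call = pc$call, trend = pc$trend,
               strength = pc$strength, n_quantified = pc$n,
               induced = induced, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
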