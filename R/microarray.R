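#' M and A values from two-color intensities
#'
#' `M = log2(cy3/cy5)` is the per-probe log2 ratio of the stress (Cy3) to
#' reference (Cy5) channel and `A = 1/2 log2(cy3 * cy5)` the average log2
#' intensity.  Probes with a non-positive intensity in either channel
#' cannot be quantified and receive `NA` in both values.
#'
#' @param cy3,cy5 numeric vectors of Cy3 (stress) and Cy5 (reference)
#'   intensities.
#' @return data.frame with columns `M` and `A`.
#' @examples
#' compute_ma(1024, 256)   # M = 2, A = 9
#' @export
compute_ma <- function(cy3, cy5) {
  stopifnot(length(cy3) == length(cy5))
  ok <- is.finite(cy3) & is.finite(cy5) & cy3 > 0 & cy5 > 0
  M <- A <- rep(NA_real_, length(cy3))
  M[ok] <- log2(cy3[ok] / cy5[ok])
  A[ok] <- 0.5 * log2(cy3[ok] * cy5[ok])
  data.frame(M = M, A = A)
}

#' Per-experiment A-value background cutoffs
#'
#' The default cutoffs are the array-specific background levels of the
#' study design, estimated from control probes: probes are retained only
#' when their average intensity lies at or above the cutoff.
#'
#' @param total_7min,total_45min,total_90min,poly_90min numeric cutoffs.
#' @return named list of cutoffs (class `array_qc_config`).
#' @export
array_qc_config <- function(total_7min = 10.27, total_45min = 10.61,
                            total_90min = 10.45, poly_90min = 10.44) {
  qc <- list(total_7min = total_7min, total_45min = total_45min,
             total_90min = total_90min, poly_90min = poly_90min)
  stopifnot(!anyNA(unlist(qc)))
  class(qc) <- "array_qc_config"
  qc
}

#' Within-array LOESS normalization
#'
#' Fits a locally weighted regression of M on A over the whole array and
#' returns `M' = M - fit(A)`, removing intensity-dependent dye bias; A
#' values are untouched.  Uses tricube-weighted local regression with
#' robustifying iterations (via [limma::loessFit()]).  If the A values are
#' (numerically) constant no curve can be fit and the function falls back
#' to centering M on its median.
#'
#' @param m,a numeric vectors of M and A values for one array.
#' @param span LOESS span (fraction of probes in each local window).
#' @param iterations number of robustness iterations.
#' @return numeric vector of normalized M values (`NA` entries propagate).
#' @export
loess_normalize <- function(m, a, span = 0.3, iterations = 2L) {
  stopifnot(length(m) == length(a))
  ok <- is.finite(m) & is.finite(a)
  if (sum(ok) < 10L)
    stop("too few probes for LOESS normalization (need >= 10)", call. = FALSE)
  out <- rep(NA_real_, length(m))
  if (stats::sd(a[ok]) < 1e-12) {
    out[ok] <- m[ok] - stats::median(m[ok])
    return(out)
  }
  fit <- limma::loessFit(m[ok], a[ok], span = span,
                         iterations = iterations + 1L)
  out[ok] <- m[ok] - fit$fitted
  out
}

#' Filter probes by average intensity
#'
#' Retains probes whose A value lies at or above the background cutoff of
#' the given experiment (the boundary is inclusive).
#'
#' @param a numeric vector of A values.
#' @param qc an [array_qc_config()].
#' @param experiment experiment key (one of the names in `qc`).
#' @return logical vector: `TRUE` for retained probes (`NA` A values are
#'   dropped).
#' @export
filter_by_avalue <- function(a, qc = array_qc_config(), experiment) {
  if (!experiment %in% names(qc))
    stop("unknown experiment key: ", experiment, call. = FALSE)
  !is.na(a) & a >= qc[[experiment]]
}

#' Combine replicate arrays into per-gene ratios
#'
#' Averages the normalized log2 ratios of a gene over replicate arrays and
#' attaches a p-value for the null hypothesis of no change.  Two methods
#' are available:
#' * `"moderated"` (default): one-sample moderated t-statistic; per-gene
#'   variances are squeezed toward a common empirical-Bayes prior across
#'   all genes of the experiment ([limma::squeezeVar()]), which restores
#'   power for designs with two biological replicates while keeping
#'   type-I control;
#' * `"t.test"`: plain two-sided one-sample t-test on the replicate
#'   values.
#'
#' Genes observed in a single replicate report their log2 ratio with an
#' undefined (`NA`) p-value; genes absent from all replicates are reported
#' as not quantified.
#'
#' @param x data.frame with columns `gene_id`, `M` (normalized log2 ratio)
#'   and `replicate`; one row per gene per replicate in which the gene
#'   survived filtering.
#' @param genes optional character vector of the full gene universe; genes
#'   missing from `x` are appended as not quantified.
#' @param method `"moderated"` or `"t.test"`.
#' @return data.frame with columns `gene_id`, `log2_ratio`, `p_value`,
#'   `n_replicates`.
#' @export
combine_replicates <- function(x, genes = NULL,
                               method = c("moderated", "t.test")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "M", "replicate") %in% names(x)))
  x <- x[is.finite(x$M), , drop = FALSE]
  sp <- split(x$M, x$gene_id)
  gid <- names(sp)
  nrep <- lengths(sp)
  mu <- vapply(sp, mean, 0)
  s2 <- vapply(sp, function(v) if (length(v) > 1L) stats::var(v) else NA_real_,
               0)
  p <- rep(NA_real_, length(gid))
  multi <- nrep >= 2L
  if (any(multi)) {
    if (method == "moderated") {
      # degenerate (noise-free) inputs give all-zero variances; the
      # resulting p-values are 0/NA and handled downstream
      sq <- suppressWarnings(limma::squeezeVar(s2[multi],
                                               df = nrep[multi] - 1L))
      df_prior <- if (is.finite(sq$df.prior)) sq$df.prior else 1e6
      tt <- mu[multi] / sqrt(sq$var.post / nrep[multi])
      p[multi] <- 2 * stats::pt(-abs(tt), df = nrep[multi] - 1L + df_prior)
    } else {
      tt <- mu[multi] / sqrt(s2[multi] / nrep[multi])
      p[multi] <- 2 * stats::pt(-abs(tt), df = nrep[multi] - 1L)
    }
  }
  out <- data.frame(gene_id = gid, log2_ratio = unname(mu),
                    p_value = unname(p), n_replicates = unname(nrep),
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, gid)
    if (length(missing))
      out <- rbind(out, data.frame(gene_id = missing, log2_ratio = NA_real_,
                                   p_value = NA_real_, n_replicates = 0L,
                                   stringsAsFactors = FALSE))
    out <- out[match(genes, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Regulation calls from log2 ratios and p-values
#'
#' A feature is called `up` when its log2 ratio is at least `up` with
#' `p < alpha`, `down` when the ratio is at most `down` with `p < alpha`,
#' and `unchanged` otherwise.  The ratio thresholds are inclusive and the
#' p-value threshold strict.  Features without a quantified ratio are
#' `not_quantified`; a quantified ratio without a defined p-value (single
#' replicate) is forced to `unchanged`.
#'
#' @param log2_ratio,p_value numeric vectors.
#' @param up,down,alpha thresholds.
#' @return character vector of calls.
#' @examples
#' call_regulated(c(0.8, 0.79, -0.8), c(0.049, 0.001, 0.04))
#' @export
call_regulated <- function(log2_ratio, p_value, up = 0.8, down = -0.8,
                           alpha = 0.05) {
  call <- ifelse(is.na(log2_ratio), "not_quantified", "unchanged")
  ok <- !is.na(log2_ratio) & !is.na(p_value) & p_value < alpha
  call[ok & log2_ratio >= up] <- "up"
  call[ok & log2_ratio <= down] <- "down"
  call
}

#' Regulation summary counts and percentages
#'
#' Counts quantified, up- and down-regulated features and expresses the
#' regulated counts as percentages of the quantified features, rounded to
#' one decimal.
#'
#' @param call character vector of calls (`up`, `down`, `unchanged`,
#'   `not_quantified`).
#' @return data.frame with columns `quantified`, `up`, `pct_up`, `down`,
#'   `pct_down`.
#' @examples
#' regulation_summary(rep(c("up", "unchanged"), c(65, 4289 - 65)))$pct_up
#' @export
regulation_summary <- function(call) {
  quant <- sum(call != "not_quantified")
  if (quant == 0L) stop("no quantified features", call. = FALSE)
  n_up <- sum(call == "up"); n_down <- sum(call == "down")
  data.frame(quantified = quant,
             up = n_up, pct_up = round(100 * n_up / quant, 1),
             down = n_down, pct_down = round(100 * n_down / quant, 1))
}

#' Full microarray quantification pipeline
#'
#' Runs the complete per-experiment workflow on a long intensity table:
#' MA computation, within-array LOESS normalization per replicate,
#' A-value background filtering, probe-to-gene averaging (after
#' normalization), replicate combination and regulation calling.
#'
#' @param arrays data.frame with columns `experiment`, `replicate`,
#'   `probe_id`, `gene_id`, `cy3`, `cy5` (as produced by
#'   [simulate_two_color_arrays()] or read from an intensity TSV).
#' @param qc an [array_qc_config()].
#' @param span,iterations LOESS parameters, see [loess_normalize()].
#' @param method replicate combination method, see [combine_replicates()].
#' @param genes optional gene universe (default: all genes in `arrays`).
#' @param up,down,alpha regulation thresholds, see [call_regulated()].
#' @return named list of per-experiment data.frames (`gene_id`,
#'   `log2_ratio`, `p_value`, `n_replicates`, `call`).
#' @export
quantify_arrays <- function(arrays, qc = array_qc_config(), span = 0.3,
                            iterations = 2L,
                            method = c("moderated", "t.test"),
                            genes = NULL, up = 0.8, down = -0.8,
                            alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(genes)) genes <- sort(unique(arrays$gene_id))
  out <- list()
  for (exp_name in unique(arrays$experiment)) {
    sub <- arrays[arrays$experiment == exp_name, , drop = FALSE]
    reps <- list()
    for (r in unique(sub$replicate)) {
      arr <- sub[sub$replicate == r, , drop = FALSE]
      ma <- compute_ma(arr$cy3, arr$cy5)
      mnorm <- loess_normalize(ma$M, ma$A, span = span,
                               iterations = iterations)
      keep <- filter_by_avalue(ma$A, qc, exp_name) & is.finite(mnorm)
      if (!any(keep)) next
      d <- data.frame(gene_id = arr$gene_id[keep], M = mnorm[keep],
                      stringsAsFactors = FALSE)
      # replicate probes of one gene are averaged after normalization
      agg <- stats::aggregate(M ~ gene_id, data = d, FUN = mean)
      agg$replicate <- r
      reps[[length(reps) + 1L]] <- agg
    }
    comb <- combine_replicates(do.call(rbind, reps), genes = genes,
                               method = method)
    comb$call <- call_regulated(comb$log2_ratio, comb$p_value,
                                up = up, down = down, alpha = alpha)
    out[[exp_name]] <- comb
  }
  out
}
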