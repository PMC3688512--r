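#' Analysis thresholds for the full pipeline
#'
#' Collects every tunable threshold of the analysis stages with the
#' study-design defaults: regulation at |log2| >= 0.8 with p < 0.05,
#' cross-layer log2 difference of 0.4, the four per-experiment A-value
#' background cutoffs, BH FDR 0.05, a minimum of two SILAC ratio counts,
#' Lys-C peptides of at least six residues with up to two missed
#' cleavages, six-frame ORFs of at least seven residues, the polarity
#' magnitude gate of 0.1 log2, and RNA-seq support gates of mean coverage
#' 10 with 80% covered positions.
#'
#' @param ... overrides for individual entries.
#' @return object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    reg_up = 0.8, reg_down = -0.8, alpha = 0.05,
    diff_threshold = 0.4,
    a_cutoff_total_7min = 10.27, a_cutoff_total_45min = 10.61,
    a_cutoff_total_90min = 10.45, a_cutoff_poly_90min = 10.44,
    fdr = 0.05, min_ratio_count = 2L,
    min_peptide_len = 6L, max_missed = 2L, min_orf_aa = 7L,
    polarity_epsilon = 0.1,
    coverage_min_mean = 10, coverage_min_frac = 0.8,
    loess_span = 0.3, loess_iterations = 2L,
    k_top = 3L, k_sub = 3L,
    combine_method = "moderated",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline_config entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' Plain YAML key-value serialization; reading back reproduces the
#' configuration exactly (round-trip identity).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Generate a complete synthetic study
#'
#' Runs all five generators (genome, regulatory scenario, arrays, SILAC
#' evidence, RNA-seq coverage) under one configuration and optionally
#' writes the bundle to disk.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory passed to [write_study_bundle()].
#' @return the study bundle: list with `config`, `genome`, `scenario`,
#'   `arrays`, `evidence`, `coverage` (and `manifest` when written).
#' @export
run_simulate <- function(config = sim_config(), dir = NULL) {
  validate_sim_config(config)
  genome <- generate_genome(config)
  scenario <- simulate_true_expression(genome, config)
  bundle <- list(config = config, genome = genome, scenario = scenario,
                 arrays = simulate_two_color_arrays(scenario, config),
                 evidence = simulate_silac_evidence(scenario, genome, config),
                 coverage = simulate_rnaseq_coverage(scenario, genome, config))
  if (!is.null(dir)) bundle$manifest <- write_study_bundle(bundle, dir)
  bundle
}

#' Run the full expressome analysis
#'
#' Executes every analysis stage in order on a study bundle: microarray
#' quantification of the transcriptome and translatome layers, SILAC
#' protein quantification, time-course selection and k-means clustering
#' with regulon kinetics, cross-layer correlation / concordance
#' integration, operon polarity calling (including the pre- versus
#' post-stress comparison on expression levels), and proteogenomic novel
#' ORF discovery with RNA-seq validation.
#'
#' @param bundle a study bundle from [run_simulate()] or
#'   [read_study_bundle()].
#' @param pconfig a [pipeline_config()].
#' @param outdir optional directory for the result tables (TSV).
#' @return named list with all stage outputs (see the individual stage
#'   functions), including `layers`, `silac`, `timecourses`, `induced`,
#'   `clusters`, `regulon_profiles`, `core_set`, `correlations`,
#'   `concordance`, `triggered`, `decline`, `master`, `polarity`,
#'   `prepost_polarity`, `proteogenomics` and `summary`.
#' @export
run_full <- function(bundle, pconfig = pipeline_config(), outdir = NULL) {
  genes <- bundle$genome$genes
  qc <- array_qc_config(total_7min = pconfig$a_cutoff_total_7min,
                        total_45min = pconfig$a_cutoff_total_45min,
                        total_90min = pconfig$a_cutoff_total_90min,
                        poly_90min = pconfig$a_cutoff_poly_90min)

  layers <- quantify_arrays(bundle$arrays, qc = qc,
                            span = pconfig$loess_span,
                            iterations = pconfig$loess_iterations,
                            method = pconfig$combine_method,
                            genes = genes$gene_id,
                            up = pconfig$reg_up, down = pconfig$reg_down,
                            alpha = pconfig$alpha)

  silac <- quantify_silac(bundle$evidence,
                          min_ratio_count = pconfig$min_ratio_count,
                          fdr = pconfig$fdr, up = pconfig$reg_up,
                          down = pconfig$reg_down)
  sp <- silac$proteins
  silac_layer <- data.frame(gene_id = sp$protein_id,
                            log2_ratio = sp$direct_log2,
                            p_value = sp$p_bh, call = sp$call,
                            stringsAsFactors = FALSE)
  silac_layer <- silac_layer[silac_layer$gene_id %in% genes$gene_id, ,
                             drop = FALSE]
  layers$silac_90min <- silac_layer

  tc <- build_timecourses(layers)
  induced <- select_induced(tc, up = pconfig$reg_up, alpha = pconfig$alpha)
  clusters <- NULL
  if (nrow(induced) >= pconfig$k_top) {
    clusters <- kmeans_cluster(induced, k = pconfig$k_top,
                               seed = pconfig$seed)
    sizes <- table(clusters$assignments)
    biggest <- names(sizes)[which.max(sizes)]
    if (sizes[biggest] >= pconfig$k_sub)
      clusters <- subdivide_cluster(clusters, biggest, pconfig$k_sub,
                                    seed = pconfig$seed + 1L)
  }
  regulon_profiles <- list(
    RpoE = regulon_kinetics(genes$gene_id[genes$regulon == "RpoE"], tc),
    RpoH2 = regulon_kinetics(genes$gene_id[genes$regulon == "RpoH2"], tc))
  core <- core_set(tc)

  pair_names <- list(c("total_90min", "poly_90min"),
                     c("total_90min", "silac_90min"),
                     c("poly_90min", "silac_90min"))
  correlations <- lapply(pair_names, function(pr) {
    cl <- correlate_layers(layers[[pr[1]]], layers[[pr[2]]])
    data.frame(layer_a = pr[1], layer_b = pr[2], n = cl$n,
               r = round(cl$r, 2), r_squared = round(cl$r_squared, 2),
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, correlations)

  triggered <- translationally_triggered(
    layers$total_90min, layers$poly_90min, up = pconfig$reg_up,
    alpha = pconfig$alpha, diff = pconfig$diff_threshold)
  decline <- protein_decline_without_rna_change(
    layers$silac_90min, layers$total_90min, down = pconfig$reg_down,
    alpha = pconfig$fdr, diff = pconfig$diff_threshold)

  ann <- genes[, c("gene_id", "operon_id", "operon_pos", "regulon")]
  master <- integrate_expressome(
    layers, annotations = ann,
    clusters = if (!is.null(clusters)) clusters$assignments,
    reg = pconfig$reg_up, diff = pconfig$diff_threshold,
    alpha = pconfig$alpha)

  polarity <- lapply(
    stats::setNames(nm = c("total_90min", "poly_90min", "silac_90min")),
    function(nm) call_polarity_all(bundle$genome$operons, genes,
                                   layers[[nm]],
                                   epsilon = pconfig$polarity_epsilon))
  prepost <- prepost_polarity_from_arrays(bundle$arrays, genes,
                                          bundle$genome$operons,
                                          polarity$total_90min,
                                          span = pconfig$loess_span,
                                          iterations = pconfig$loess_iterations)

  evpep <- unique(bundle$evidence$peptide[
    bundle$evidence$sample %in% c("reference_mix", "stress_mix")])
  pg <- discover_novel_orfs(
    bundle$genome$sequence,
    annotated = data.frame(seq_id = genes$gene_id, aa = genes$protein,
                           stringsAsFactors = FALSE),
    peptides = evpep, track = bundle$coverage,
    min_aa = pconfig$min_orf_aa, min_peptides = 2L,
    max_missed = pconfig$max_missed,
    min_mean = pconfig$coverage_min_mean,
    min_frac = pconfig$coverage_min_frac)

  summary_tab <- do.call(rbind, lapply(names(layers), function(nm) {
    s <- regulation_summary(layers[[nm]]$call)
    cbind(data.frame(experiment = nm, stringsAsFactors = FALSE), s)
  }))

  results <- list(layers = layers, silac = silac, timecourses = tc,
                  induced = induced, clusters = clusters,
                  regulon_profiles = regulon_profiles, core_set = core,
                  correlations = correlations, triggered = triggered,
                  decline = decline, master = master, polarity = polarity,
                  prepost_polarity = prepost, proteogenomics = pg,
                  summary = summary_tab, pconfig = pconfig)
  if (!is.null(outdir)) write_results(results, outdir)
  results
}

# Per-gene log2 expression levels at 0 and 90 min from the total_90min
# arrays (Cy5 = reference level, Cy3 = stressed level), dye-bias corrected
# by splitting the normalized M symmetrically around A, then averaged over
# replicates; polarity strengths are compared pre versus post stress for
# operons called on the transcriptome layer.
prepost_polarity_from_arrays <- function(arrays, genes, operons,
                                         polarity_total, span = 0.3,
                                         iterations = 2L) {
  sub <- arrays[arrays$experiment == "total_90min", , drop = FALSE]
  lv <- list()
  for (r in unique(sub$replicate)) {
    arr <- sub[sub$replicate == r, , drop = FALSE]
    ma <- compute_ma(arr$cy3, arr$cy5)
    mn <- loess_normalize(ma$M, ma$A, span = span, iterations = iterations)
    lv[[length(lv) + 1L]] <- data.frame(
      gene_id = arr$gene_id, l0 = ma$A - mn / 2, l90 = ma$A + mn / 2,
      stringsAsFactors = FALSE)
  }
  lv <- do.call(rbind, lv)
  l0 <- tapply(lv$l0, lv$gene_id, mean)
  l90 <- tapply(lv$l90, lv$gene_id, mean)
  called <- polarity_total$operon_id[!is.na(polarity_total$call)]
  rows <- lapply(called, function(oid) {
    members <- genes[genes$operon_id %in% oid, , drop = FALSE]
    members <- members[order(members$operon_pos), , drop = FALSE]
    cp <- compare_prepost_polarity(unname(l0[members$gene_id]),
                                   unname(l90[members$gene_id]))
    data.frame(operon_id = oid, strength_0 = cp$strength_0,
               strength_90 = cp$strength_90, delta = cp$delta,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(operon_id = character(0), strength_0 = numeric(0),
               strength_90 = numeric(0), delta = numeric(0))
}

#' Write pipeline result tables
#'
#' @param results a [run_full()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
write_results <- function(results, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(results$master, "master_expressome.tsv")
  tsv(results$summary, "regulation_summary.tsv")
  tsv(results$correlations, "layer_correlations.tsv")
  tsv(results$silac$proteins, "protein_quant.tsv")
  if (!is.null(results$clusters))
    tsv(data.frame(gene_id = names(results$clusters$assignments),
                   cluster = unname(results$clusters$assignments)),
        "cluster_assignments.tsv")
  for (nm in names(results$polarity))
    tsv(results$polarity[[nm]], paste0("polarity_", nm, ".tsv"))
  tsv(results$prepost_polarity, "polarity_prepost.tsv")
  tsv(results$proteogenomics$novel_calls, "novel_orf_calls.tsv")
  files <- list.files(outdir, pattern = "\\.tsv$")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Score pipeline results against the planted truth
#'
#' Computes sensitivity and precision for every call type of a synthetic
#' run: up/down regulation per layer, pairwise concordance classes,
#' translationally-triggered and protein-decline detectors, operon
#' polarity per layer, and supported novel ORF discovery.  Truth labels
#' are derived from the planted effects with the same thresholds the
#' pipeline uses (regulation 0.8, difference 0.4); metrics are computed
#' over features quantified in the layers each call needs.
#'
#' @param results a [run_full()] result.
#' @param bundle the study bundle the results were computed from.
#' @return data.frame with columns `metric`, `layer`, `class`, `tp`,
#'   `fp`, `fn`, `sensitivity`, `precision`.
#' @export
evaluate_against_truth <- function(results, bundle) {
  eff <- bundle$scenario$effects
  layer_col <- c(total_7min = "t7", total_45min = "t45",
                 total_90min = "t90", poly_90min = "poly90",
                 silac_90min = "silac90")
  rows <- list()
  add <- function(metric, layer, class, truth, pred) {
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    fn <- sum(truth & !pred)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, layer = layer, class = class, tp = tp, fp = fp,
      fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      stringsAsFactors = FALSE)
  }

  for (nm in names(layer_col)) {
    lt <- results$layers[[nm]]
    if (is.null(lt)) next
    if (!all(lt$gene_id %in% eff$gene_id))
      stop("truth/result gene-id mismatch in layer ", nm, call. = FALSE)
    e <- eff[[layer_col[[nm]]]][match(lt$gene_id, eff$gene_id)]
    q <- lt$call != "not_quantified"
    add("regulation", nm, "up", (e >= 0.8)[q], (lt$call == "up")[q])
    add("regulation", nm, "down", (e <= -0.8)[q], (lt$call == "down")[q])
  }

  pairs <- list(c("total_90min", "poly_90min"),
                c("total_90min", "silac_90min"),
                c("poly_90min", "silac_90min"))
  for (pr in pairs) {
    col <- paste0("concordance_", pr[1], "_vs_", pr[2])
    if (!col %in% names(results$master)) next
    m <- results$master
    ea <- eff[[layer_col[[pr[1]]]]][match(m$gene_id, eff$gene_id)]
    eb <- eff[[layer_col[[pr[2]]]]][match(m$gene_id, eff$gene_id)]
    truth_cls <- ifelse(pmax(abs(ea), abs(eb)) >= 0.8,
                        ifelse(abs(ea - eb) < 0.4, "unidirectional",
                               "biased"), "unchanged")
    ok <- !is.na(m[[col]])
    for (cls in c("unidirectional", "biased"))
      add("concordance", paste(pr, collapse = "_vs_"), cls,
          (truth_cls == cls)[ok], (m[[col]] == cls)[ok])
  }

  # planted four-way concordance classes: evaluated over the planted
  # single-gene classes (operon members are scored by the polarity
  # metrics), restricted to genes quantified in the layers each class
  # needs (both RNA layers; the proteome additionally for protein_decline)
  cls_t <- bundle$scenario$classes
  total <- results$layers$total_90min
  poly <- results$layers$poly_90min
  sil <- results$layers$silac_90min
  rna_q <- total$gene_id[total$call != "not_quantified" &
                           poly$call[match(total$gene_id, poly$gene_id)] !=
                           "not_quantified"]
  cc_tp <- classify_concordance(total, poly)
  pred4 <- function(ids) {
    p_t <- ids %in% results$triggered
    p_d <- ids %in% results$decline
    p_u <- cc_tp$class[match(ids, cc_tp$gene_id)] %in% "unidirectional" &
      !p_t & !p_d
    cls <- ifelse(p_t, "translational_only",
                  ifelse(p_d, "protein_decline",
                         ifelse(p_u, "unidirectional", "unchanged")))
    cls
  }
  planted <- cls_t$concordance_class[match(rna_q, cls_t$gene_id)]
  keep <- !is.na(planted)
  ids <- rna_q[keep]; planted <- planted[keep]
  pred <- pred4(ids)
  for (cls in c("unidirectional", "translational_only", "unchanged"))
    add("concordance_class", "planted", cls, planted == cls, pred == cls)
  in_sil <- ids %in% sil$gene_id[!is.na(sil$log2_ratio)]
  add("concordance_class", "planted", "protein_decline",
      (planted == "protein_decline")[in_sil],
      (pred == "protein_decline")[in_sil])

  pol_truth <- bundle$scenario$operon_polarity
  for (nm in names(results$polarity)) {
    pt <- results$polarity[[nm]]
    truth <- pol_truth$polarity[match(pt$operon_id, pol_truth$operon_id)]
    if (nm == "poly_90min")
      truth[pol_truth$translatome_only[
        match(pt$operon_id, pol_truth$operon_id)]] <- "5prime"
    called <- !is.na(pt$call) & truth != "not_induced"
    for (cls in c("5prime", "3prime"))
      add("polarity", nm, cls, (truth == cls)[called],
          (pt$call == cls)[called])
    # aggregate polar call (either direction; direction must match)
    add("polarity", nm, "polar",
        (truth %in% c("5prime", "3prime"))[called],
        (pt$call == truth & truth %in% c("5prime", "3prime"))[called] |
          ((pt$call %in% c("5prime", "3prime")) &
             !truth %in% c("5prime", "3prime"))[called])
  }
  # translatome-only polarity flagging
  flag <- vapply(results$polarity$total_90min$operon_id, function(oid) {
    calls <- c(
      total_90min = results$polarity$total_90min$call[
        results$polarity$total_90min$operon_id == oid],
      poly_90min = results$polarity$poly_90min$call[
        results$polarity$poly_90min$operon_id == oid])
    polarity_concordance_across_layers(calls)$translatome_only
  }, NA)
  add("polarity", "cross_layer", "translatome_only",
      pol_truth$translatome_only[match(results$polarity$total_90min$operon_id,
                                       pol_truth$operon_id)],
      flag)

  # novel ORF discovery
  # planted novel ORF coordinates are the stop-to-stop stretches the
  # six-frame scan reproduces, so matching is exact
  nov_truth <- bundle$genome$novel_orfs
  calls <- results$proteogenomics$novel_calls
  call_key <- if (nrow(calls))
    paste(calls$start, calls$end, calls$strand) else character(0)
  truth_key <- paste(nov_truth$start, nov_truth$end, nov_truth$strand)
  matched <- call_key %in% truth_key
  supported <- if ("rnaseq_status" %in% names(calls))
    calls$rnaseq_status == "supported" else rep(NA, nrow(calls))
  truth_hit <- truth_key %in% call_key
  sup_hit <- truth_key %in% call_key[supported]
  add("novel_orf", "proteome", "called", rep(TRUE, nrow(nov_truth)),
      truth_hit)
  add("novel_orf", "rnaseq", "supported", nov_truth$expressed, sup_hit)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "novel_orf", layer = "proteome", class = "false_novel",
    tp = NA_integer_, fp = sum(!matched), fn = NA_integer_,
    sensitivity = NA_real_, precision = NA_real_, stringsAsFactors = FALSE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
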