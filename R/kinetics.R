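#' Build gene time-courses from per-experiment ratio tables
#'
#' Joins the three total-RNA experiments into one table with log2 ratios,
#' p-values and calls at 7, 45 and 90 min.
#'
#' @param layers named list of per-experiment tables as returned by
#'   [quantify_arrays()]; must contain `total_7min`, `total_45min` and
#'   `total_90min`.
#' @return data.frame with columns `gene_id`, `log2_7`, `log2_45`,
#'   `log2_90`, `p_7`, `p_45`, `p_90`, `call_7`, `call_45`, `call_90`.
#' @export
build_timecourses <- function(layers) {
  need <- c("total_7min", "total_45min", "total_90min")
  stopifnot(all(need %in% names(layers)))
  ids <- layers$total_7min$gene_id
  pick <- function(exp_name, field) {
    t <- layers[[exp_name]]
    t[[field]][match(ids, t$gene_id)]
  }
  data.frame(gene_id = ids,
             log2_7 = pick("total_7min", "log2_ratio"),
             log2_45 = pick("total_45min", "log2_ratio"),
             log2_90 = pick("total_90min", "log2_ratio"),
             p_7 = pick("total_7min", "p_value"),
             p_45 = pick("total_45min", "p_value"),
             p_90 = pick("total_90min", "p_value"),
             call_7 = pick("total_7min", "call"),
             call_45 = pick("total_45min", "call"),
             call_90 = pick("total_90min", "call"),
             stringsAsFactors = FALSE)
}

#' Select stress-induced genes
#'
#' A gene is included when it shows significant induction (log2 ratio at
#' least `up` with p-value below `alpha`) at one of the three time-points.
#'
#' @param tc a [build_timecourses()] table.
#' @param up,alpha induction thresholds.
#' @return the selected subset of `tc`.
#' @export
select_induced <- function(tc, up = 0.8, alpha = 0.05) {
  hit <- function(l, p) !is.na(l) & !is.na(p) & l >= up & p < alpha
  keep <- hit(tc$log2_7, tc$p_7) | hit(tc$log2_45, tc$p_45) |
    hit(tc$log2_90, tc$p_90)
  tc[keep, , drop = FALSE]
}

#' k-means clustering of expression time-courses
#'
#' Clusters the (7, 45, 90 min) log2 ratio vectors by k-means with
#' Euclidean distance and at most `max_iter` iterations (Lloyd updates),
#' seeded by sampling `k` distinct genes as initial centroids under an
#' explicit seed, so results are reproducible.  Genes with a missing
#' ratio at any time-point are excluded (complete cases).  If an update
#' empties a cluster its centroid is re-seeded from the point farthest
#' from its assigned centroid.
#'
#' @param tc a [build_timecourses()] table (typically after
#'   [select_induced()]).
#' @param k number of clusters.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of iterations.
#' @return list of class `cluster_result`: `assignments` (named cluster
#'   labels per gene), `centroids` (k x 3 matrix), `iterations`, `k`,
#'   `seed`, `tot_withinss`.
#' @export
kmeans_cluster <- function(tc, k, seed = 1L, max_iter = 50L) {
  m <- as.matrix(tc[, c("log2_7", "log2_45", "log2_90")])
  rownames(m) <- tc$gene_id
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (k > nrow(m))
    stop("k exceeds the number of complete time-courses", call. = FALSE)
  set.seed(seed)
  centers <- m[sample.int(nrow(m), k), , drop = FALSE]
  assign_to <- function(cent) {
    d <- vapply(seq_len(nrow(cent)), function(j)
      colSums((t(m) - cent[j, ])^2), numeric(nrow(m)))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_to(centers)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      if (!any(cl == j)) {
        # re-seed an emptied cluster from the farthest point
        d <- rowSums((m - centers[cl, , drop = FALSE])^2)
        centers[j, ] <- m[which.max(d), ]
      } else {
        centers[j, ] <- colMeans(m[cl == j, , drop = FALSE])
      }
    }
    cl_new <- assign_to(centers)
    if (identical(cl_new, cl) || iter >= max_iter) { cl <- cl_new; break }
    cl <- cl_new
  }
  wss <- sum((m - centers[cl, , drop = FALSE])^2)
  structure(list(assignments = stats::setNames(as.character(cl), rownames(m)),
                 centroids = centers, iterations = iter, k = k, seed = seed,
                 tot_withinss = wss, data = m),
            class = "cluster_result")
}

#' Subdivide one cluster
#'
#' Re-runs k-means on the members of a single cluster; the sub-cluster
#' labels are the parent label suffixed with letters (e.g. `2a`, `2b`,
#' `2c`).
#'
#' @param result a [kmeans_cluster()] result.
#' @param cluster_id label of the cluster to subdivide.
#' @param k2 number of sub-clusters.
#' @param seed seed for the sub-clustering.
#' @param max_iter maximum iterations.
#' @return a `cluster_result` whose `assignments` cover all genes, with
#'   the subdivided cluster relabeled.
#' @export
subdivide_cluster <- function(result, cluster_id, k2, seed = 1L,
                              max_iter = 50L) {
  members <- names(result$assignments)[result$assignments == cluster_id]
  if (!length(members)) stop("cluster is empty", call. = FALSE)
  m <- result$data[members, , drop = FALSE]
  sub_tc <- data.frame(gene_id = rownames(m), log2_7 = m[, 1],
                       log2_45 = m[, 2], log2_90 = m[, 3],
                       stringsAsFactors = FALSE)
  sub <- kmeans_cluster(sub_tc, k = k2, seed = seed, max_iter = max_iter)
  lab <- paste0(cluster_id, letters[as.integer(sub$assignments)])
  out <- result
  out$assignments[members] <- stats::setNames(lab, names(sub$assignments))[members]
  out$sub_result <- sub
  out
}

#' Mean expression kinetics of a regulon
#'
#' Members are first filtered to those exhibiting a log2 ratio of at
#' least `min_log2` at one or more time-points; the profile is the
#' per-time-point mean over the retained members.
#'
#' @param members character vector of member gene ids.
#' @param tc a [build_timecourses()] table.
#' @param min_log2 membership expression filter.
#' @return list with `profile` (named means at 7, 45, 90 min; `NA`s when
#'   no member passes) and `n` (members retained).
#' @export
regulon_kinetics <- function(members, tc, min_log2 = 0.8) {
  sub <- tc[tc$gene_id %in% members, , drop = FALSE]
  m <- as.matrix(sub[, c("log2_7", "log2_45", "log2_90")])
  keep <- apply(m, 1, function(v) any(!is.na(v) & v >= min_log2))
  m <- m[keep, , drop = FALSE]
  if (!nrow(m))
    return(list(profile = c(t7 = NA_real_, t45 = NA_real_, t90 = NA_real_),
                n = 0L))
  list(profile = stats::setNames(colMeans(m, na.rm = TRUE),
                                 c("t7", "t45", "t90")),
       n = nrow(m))
}

#' Core set of persistently induced genes
#'
#' Genes called up at all three time-points.
#'
#' @param tc a [build_timecourses()] table.
#' @return character vector of gene ids.
#' @export
core_set <- function(tc) {
  tc$gene_id[tc$call_7 == "up" & tc$call_45 == "up" & tc$call_90 == "up"]
}
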