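tc_frame <- function(l7, l45, l90, p7 = 0.01, p45 = 0.01, p90 = 0.01,
                     ids = NULL) {
  n <- length(l7)
  data.frame(gene_id = ids %||% sprintf("g%03d", seq_len(n)),
             log2_7 = l7, log2_45 = l45, log2_90 = l90,
             p_7 = rep_len(p7, n), p_45 = rep_len(p45, n),
             p_90 = rep_len(p90, n),
             call_7 = "unchanged", call_45 = "unchanged",
             call_90 = "unchanged", stringsAsFactors = FALSE)
}

test_that("induced genes need one significant time-point", {
  tc <- tc_frame(l7 = c(0.2, 0.7, 0.9), l45 = c(0.9, 0.7, 0.9),
                 l90 = c(0.3, 0.7, 0.9),
                 p7 = c(0.5, 0.01, 0.2), p45 = c(0.01, 0.01, 0.2),
                 p90 = c(0.5, 0.01, 0.2))
  sel <- select_induced(tc)
  expect_equal(sel$gene_id, "g001")  # g2 below ratio, g3 fails the p gate
})

test_that("k-means separates separable profiles and is seed-stable", {
  tc <- tc_frame(l7 = c(rep(1, 5), rep(0, 5), rep(1, 5)),
                 l45 = c(rep(1, 5), rep(1, 5), rep(0, 5)),
                 l90 = c(rep(1, 5), rep(1, 5), rep(0, 5)))
  truth <- rep(1:3, each = 5)
  res <- kmeans_cluster(tc, k = 3, seed = 4)
  expect_equal(rand_index_adjusted(res$assignments, truth), 1)
  expect_identical(kmeans_cluster(tc, k = 3, seed = 4)$assignments,
                   res$assignments)
  # permutation-equivalence across seeds on separable data
  expect_equal(rand_index_adjusted(
    kmeans_cluster(tc, k = 3, seed = 99)$assignments, truth), 1)
  expect_lte(res$iterations, 50L)
  # k = 1: centroid is the coordinate-wise mean
  res1 <- kmeans_cluster(tc, k = 1, seed = 1)
  expect_equal(unname(res1$centroids[1, ]),
               unname(colMeans(as.matrix(tc[, 2:4]))))
  expect_error(kmeans_cluster(tc[1:2, ], k = 3), "exceeds")
})

test_that("the Lloyd updates agree with the reference implementation", {
  set.seed(55)
  n <- 120
  tc <- tc_frame(l7 = stats::rnorm(n, rep(c(0, 2), each = n / 2), 0.3),
                 l45 = stats::rnorm(n, rep(c(0, 2), each = n / 2), 0.3),
                 l90 = stats::rnorm(n, rep(c(2, 0), each = n / 2), 0.3))
  m <- as.matrix(tc[, c("log2_7", "log2_45", "log2_90")])
  ours <- kmeans_cluster(tc, k = 2, seed = 6)
  set.seed(6)
  centers <- m[sample.int(nrow(m), 2), ]
  ref <- stats::kmeans(m, centers = centers, algorithm = "Lloyd",
                       iter.max = 50)
  expect_equal(rand_index_adjusted(ours$assignments, ref$cluster), 1)
  expect_equal(sort(ours$tot_withinss), sort(ref$tot.withinss),
               tolerance = 1e-8)
})

test_that("subdividing relabels members with letter suffixes", {
  # three separable profile groups inside one parent cluster
  tc <- tc_frame(l7 = c(rep(1, 3), rep(0, 3), rep(1, 3)),
                 l45 = c(rep(1, 3), rep(1, 3), rep(0, 3)),
                 l90 = c(rep(1, 3), rep(1, 3), rep(0, 3)))
  res <- kmeans_cluster(tc, k = 1, seed = 2)
  sub <- subdivide_cluster(res, "1", k2 = 3, seed = 3)
  labs <- sub$assignments
  expect_true(all(grepl("^1[abc]$", labs)))
  expect_equal(rand_index_adjusted(labs, rep(1:3, each = 3)), 1)
  # k2 = 1 keeps the cluster whole under a single suffix
  sub1 <- subdivide_cluster(res, "1", k2 = 1, seed = 3)
  expect_true(all(sub1$assignments == "1a"))
  # subdividing a singleton with k2 = 1 returns that singleton
  solo <- kmeans_cluster(tc[1, ], k = 1, seed = 1)
  sub_solo <- subdivide_cluster(solo, "1", k2 = 1, seed = 1)
  expect_equal(unname(sub_solo$assignments), "1a")
})

test_that("regulon kinetics filter members before averaging", {
  tc <- tc_frame(l7 = c(1, 3, 0.2), l45 = c(2, 2, 0.5),
                 l90 = c(3, 1, 0.3), ids = c("a", "b", "weak"))
  rk <- regulon_kinetics(c("a", "b", "weak"), tc)
  expect_equal(unname(rk$profile), c(2, 2, 2))
  expect_equal(rk$n, 2L)  # 'weak' never reaches 0.8 and is excluded
  # profile means stay within member bounds
  expect_true(all(rk$profile >= c(1, 2, 1) & rk$profile <= c(3, 2, 3)))
  none <- regulon_kinetics("weak", tc)
  expect_equal(none$n, 0L)
  expect_true(all(is.na(none$profile)))
})

test_that("planted regulons reproduce immediate versus delayed kinetics", {
  run <- default_run()
  prof <- run$results$regulon_profiles
  expect_gte(prof$RpoE$profile[["t7"]], 0.8)
  expect_lt(prof$RpoH2$profile[["t7"]], 0.8)
  expect_gte(prof$RpoH2$profile[["t45"]], 0.8)
})

test_that("the core set is the always-up subset of induced genes", {
  tc <- tc_frame(l7 = c(1, 1), l45 = c(1, 1), l90 = c(1, 1),
                 ids = c("all3", "two"))
  tc$call_7 <- c("up", "up"); tc$call_45 <- c("up", "up")
  tc$call_90 <- c("up", "unchanged")
  expect_equal(core_set(tc), "all3")
  # core is a subset of the induced selection, and the planted
  # immediate class is recovered as the core set
  run <- default_run()
  tc_run <- run$results$timecourses
  expect_true(all(run$results$core_set %in%
                    select_induced(tc_run)$gene_id))
  planted <- run$bundle$scenario$classes
  immediate <- planted$gene_id[planted$kinetic_class == "immediate"]
  expect_gte(length(intersect(run$results$core_set, immediate)) /
               length(immediate), 0.9)
})
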