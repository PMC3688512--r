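test_that("M and A values follow their definitions", {
  ma <- compute_ma(c(1024, 512, 2048, -1, 100), c(256, 512, 2048, 100, 0))
  expect_equal(ma$M[1:3], c(2, 0, 0))
  expect_equal(ma$A[1:3], c(9, 9, 11))
  expect_true(all(is.na(ma$M[4:5])))
  expect_true(all(is.na(ma$A[4:5])))
})

test_that("LOESS normalization removes a smooth injected bias", {
  set.seed(21)
  a <- stats::runif(1500, 8, 14)
  bias <- 0.5 * sin(a / 2)
  # noise-free all-null array: the bias is essentially the fitted curve
  m1 <- loess_normalize(bias, a)
  expect_lt(max(abs(m1)), 0.1 * max(abs(bias)))
  # without bias, normalization is a near-constant shift
  a_big <- stats::runif(10000, 8, 14)
  m <- stats::rnorm(10000, 0, 0.2)
  m2 <- loess_normalize(m, a_big)
  expect_gt(stats::cor(m, m2), 0.999)
  # identical M values: fit equals the constant, all residuals zero
  m3 <- loess_normalize(rep(0.7, 100), a[1:100])
  expect_equal(m3, rep(0, 100), tolerance = 1e-12)
})

test_that("LOESS normalization handles degenerate inputs as documented", {
  expect_error(loess_normalize(1:5, 1:5), "too few probes")
  # constant A: documented fallback is median centering
  m <- c(0.5, 1.5, 1, 2, 0, 1, 1, 1, 1, 1)
  out <- loess_normalize(m, rep(10, 10))
  expect_equal(out, m - stats::median(m))
  # NA probes propagate without disturbing the rest
  m2 <- c(stats::rnorm(50), NA)
  a2 <- c(stats::runif(50, 8, 14), NA)
  out2 <- loess_normalize(m2, a2)
  expect_true(is.na(out2[51]))
  expect_equal(sum(is.finite(out2)), 50L)
})

test_that("re-normalizing an already normalized array is a small perturbation", {
  # a locally weighted fit of residuals is close to, but not exactly,
  # zero; the refit changes M by far less than the bias it removed
  set.seed(22)
  a <- stats::runif(1500, 8, 14)
  m <- 0.5 * sin(a / 2) + stats::rnorm(1500, 0, 0.2)
  m1 <- loess_normalize(m, a)
  m2 <- loess_normalize(m1, a)
  expect_lt(max(abs(m2 - m1)), 0.05)
})

test_that("A-value filtering uses inclusive per-experiment cutoffs", {
  qc <- array_qc_config()
  expect_true(filter_by_avalue(10.45, qc, "total_90min"))
  expect_false(filter_by_avalue(10.44, qc, "total_90min"))
  expect_true(filter_by_avalue(10.44, qc, "poly_90min"))
  expect_true(filter_by_avalue(10.27, qc, "total_7min"))
  expect_true(filter_by_avalue(10.61, qc, "total_45min"))
  expect_false(filter_by_avalue(10.60, qc, "total_45min"))
  qc_inf <- array_qc_config(total_90min = -Inf)
  expect_true(all(filter_by_avalue(c(0.1, 5, 20), qc_inf, "total_90min")))
  expect_error(filter_by_avalue(11, qc, "poly_45min"), "unknown experiment")
})

test_that("replicate combination averages ratios and tests against zero", {
  x <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                  M = c(1, 1, 0.9, -0.9), replicate = c(1, 2, 1, 2))
  out <- combine_replicates(x, method = "t.test")
  expect_equal(out$log2_ratio[out$gene_id == "g1"], 1)
  expect_equal(out$log2_ratio[out$gene_id == "g2"], 0)
  expect_gt(out$p_value[out$gene_id == "g2"], 0.5)
  # four near-identical replicates at the threshold are significant
  set.seed(1)
  x4 <- data.frame(gene_id = "g", M = 0.8 + stats::rnorm(4, 0, 1e-3),
                   replicate = 1:4)
  expect_lt(combine_replicates(x4, method = "t.test")$p_value, 0.05)
  # single surviving replicate: ratio reported, p undefined
  x1 <- data.frame(gene_id = "g", M = 1.2, replicate = 1)
  out1 <- combine_replicates(x1, genes = c("g", "absent"))
  expect_equal(out1$log2_ratio[1], 1.2)
  expect_true(is.na(out1$p_value[1]))
  expect_equal(out1$n_replicates[out1$gene_id == "absent"], 0L)
  expect_equal(call_regulated(out1$log2_ratio, out1$p_value),
               c("unchanged", "not_quantified"))
})

test_that("moderated combination is calibrated on duplicate null arrays", {
  set.seed(33)
  n <- 2000L
  x <- data.frame(gene_id = rep(sprintf("g%04d", 1:n), each = 2),
                  M = stats::rnorm(2 * n, 0, 0.21),
                  replicate = rep(1:2, n))
  out <- combine_replicates(x, method = "moderated")
  calls <- call_regulated(out$log2_ratio, out$p_value)
  # nominal rate of |mean| >= 0.8 under N(0, 0.15) is ~1e-7; no calls
  # expected within the binomial CI at n = 2000
  expect_equal(sum(calls != "unchanged"), 0L)
  # and p-values are roughly uniform (not anti-conservative)
  expect_lt(mean(out$p_value < 0.05), 0.05 +
              1.96 * sqrt(0.05 * 0.95 / n))
})

test_that("regulation calls use inclusive ratio and strict p thresholds", {
  expect_equal(call_regulated(0.80, 0.049), "up")
  expect_equal(call_regulated(0.79, 0.001), "unchanged")
  expect_equal(call_regulated(-0.8, 0.04), "down")
  expect_equal(call_regulated(0.9, 0.05), "unchanged")  # p not < 0.05
  expect_equal(call_regulated(NA, 0.01), "not_quantified")
})

test_that("regulation summaries partition quantified genes", {
  calls <- c(rep("up", 7), rep("down", 3), rep("unchanged", 40),
             rep("not_quantified", 10))
  s <- regulation_summary(calls)
  expect_equal(s$quantified, 50L)
  expect_equal(s$up + s$down + sum(calls == "unchanged"), s$quantified)
  expect_equal(s$pct_up, round(100 * 7 / 50, 1))
  expect_equal(regulation_summary(c("up", "unchanged"))$pct_down, 0)
  expect_error(regulation_summary(rep("not_quantified", 5)),
               "no quantified")
})

test_that("calls recover planted effects from quadruplicate arrays", {
  set.seed(44)
  n <- 1000L
  truth <- c(rep(1.5, 50), rep(-1.5, 50), rep(0, n - 100))
  x <- data.frame(gene_id = rep(sprintf("g%04d", 1:n), each = 4),
                  M = rep(truth, each = 4) + stats::rnorm(4 * n, 0, 0.15),
                  replicate = rep(1:4, n))
  out <- combine_replicates(x, method = "t.test")
  calls <- call_regulated(out$log2_ratio, out$p_value)
  truth_o <- truth[match(out$gene_id, sprintf("g%04d", 1:n))]
  sens_up <- sum(calls == "up" & truth_o > 0) / sum(truth_o > 0)
  prec_up <- sum(calls == "up" & truth_o > 0) / sum(calls == "up")
  sens_dn <- sum(calls == "down" & truth_o < 0) / sum(truth_o < 0)
  expect_gte(sens_up, 0.9); expect_gte(prec_up, 0.9)
  expect_gte(sens_dn, 0.9)
})

test_that("the array pipeline keeps probes above background only", {
  b <- small_bundle()
  layers <- quantify_arrays(b$arrays)
  lt <- layers$total_90min
  expect_setequal(lt$gene_id, b$genome$genes$gene_id)
  # low-expression genes (baseline below every cutoff) are not quantified
  base <- b$scenario$baseline
  low <- names(base)[base < 9.6]
  expect_gt(length(low), 0L)
  expect_true(all(lt$call[match(low, lt$gene_id)] == "not_quantified"))
})
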