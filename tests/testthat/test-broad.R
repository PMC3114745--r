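test_that("convolution null composes point masses and symmetry", {
  # two samples with point-mass histograms at 0.10 and 0.20 -> mass at 0.30
  low <- cbind(rep(0.10, 5), rep(0.20, 5))
  null <- build_null(low, 0.01)
  expect_equal(sum(null$mass > 1e-12), 1L)
  centre <- (null$offset + which(null$mass > 0.5) - 1) * null$bin_width
  expect_equal(centre, 0.30, tolerance = 1e-9)

  # symmetric per-sample histograms give a symmetric null
  sym <- cbind(c(-0.05, 0, 0.05), c(-0.02, 0, 0.02))
  ns <- build_null(sym, 0.01)
  expect_near(ns$mass, rev(ns$mass), 1e-12)
  expect_equal(sum(ns$mass), 1, tolerance = 1e-6)
})

test_that("null mean and variance add across samples", {
  set.seed(60)
  low <- matrix(rnorm(500 * 4, sd = 0.05), 500, 4)
  null <- build_null(low, 0.01)
  centres <- (null$offset + seq_along(null$mass) - 1) * null$bin_width
  null_mean <- sum(centres * null$mass)
  binned_means <- colSums(round(low / 0.01) * 0.01) / nrow(low)
  expect_equal(null_mean, sum(binned_means), tolerance = 1e-6)
  # S identical samples: variance = S x per-sample histogram variance
  rep4 <- low[, c(1, 1, 1, 1)]
  n4 <- build_null(rep4, 0.01)
  c4 <- (n4$offset + seq_along(n4$mass) - 1) * n4$bin_width
  v1 <- {
    k <- round(low[, 1] / 0.01) * 0.01
    mean(k^2) - mean(k)^2
  }
  v4 <- sum(c4^2 * n4$mass) - sum(c4 * n4$mass)^2
  expect_equal(v4, 4 * v1, tolerance = 1e-3)
})

test_that("null tails match Monte-Carlo sums of independent draws", {
  set.seed(61)
  low <- cbind(rnorm(400, 0.02, 0.04), rnorm(400, -0.01, 0.05),
               rnorm(400, 0, 0.03))
  null <- build_null(low, 0.01)
  mc <- rowSums(vapply(1:3, function(j) {
    round(sample(low[, j], 1e5, replace = TRUE) / 0.01) * 0.01
  }, numeric(1e5)))
  for (q in c(0.10, 0.05, 0.01, 0.002)) {
    thr <- round(stats::quantile(mc, 1 - q) / 0.01) * 0.01
    p_conv <- broad_pvalues(thr, null)$p_amp
    p_mc <- mean(mc >= thr - 1e-9)
    if (p_mc >= 1e-3) expect_lt(abs(p_conv - p_mc) / p_mc, 0.10)
  }
})

test_that("tail p-values include the observed bin and behave monotonically", {
  low <- cbind(c(-0.02, 0, 0.02), c(-0.02, 0, 0.02))
  null <- build_null(low, 0.01)
  centres <- (null$offset + seq_along(null$mass) - 1) * null$bin_width
  top_bin <- max(which(null$mass > 1e-15))
  pv <- broad_pvalues(centres[top_bin], null)
  expect_equal(pv$p_amp, sum(null$mass[top_bin:length(null$mass)]),
               tolerance = 1e-9)
  # symmetric null: both tail p-values at the median include >= half the mass
  mid <- broad_pvalues(0, null)
  expect_gte(mid$p_amp, 0.5)
  expect_gte(mid$p_del, 0.5)
  expect_equal(mid$p_amp, mid$p_del, tolerance = 1e-9)
  # p_amp non-increasing across the scanned grid
  grid <- seq(min(centres) - 0.05, max(centres) + 0.05, by = 0.005)
  pa <- suppressWarnings(broad_pvalues(grid, null)$p_amp)
  expect_true(all(diff(pa) <= 1e-12))
  expect_warning(broad_pvalues(max(centres) + 1, null), "outside")
})

test_that("q-values implement the fixed-lambda Storey procedure", {
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(qvalues(numeric(0)), numeric(0))

  # hand-evaluated step-up formula with the null proportion fixed at 1
  p <- c(0.01, 0.02, 0.04, 0.08)
  expect_near(qvalues(p, pi0 = 1), c(0.04, 0.04, 0.16 / 3, 0.08), 1e-12)
  # the estimated pi0 here is 0 (no p exceeds 0.5): everything is called
  expect_equal(qvalues(p), rep(0, 4))

  # mixed p-values: q equals pi0 x BH for this configuration
  set.seed(62)
  p2 <- c(runif(50, 0, 0.1), runif(150, 0, 1))
  pi0_2 <- min(1, sum(p2 > 0.5) / (0.5 * length(p2)))
  bh <- stats::p.adjust(p2, "BH")
  expect_near(qvalues(p2), pmin(pi0_2 * bh, 1), 1e-12)
  expect_true(all(qvalues(p2) <= bh + 1e-12))
})

test_that("arm calls require the configured fraction of significant probes", {
  chrom <- rep("chr1", 10)
  pos <- as.integer(1:10 * 100)
  arms <- region_annotation("chr1", 0, 1000, "1p", kind = "arms")
  q_all <- rep(0.001, 10)
  q_one <- c(rep(0.001, 9), 0.5)
  all_sig <- call_broad_arms(chrom, pos, q_all, rep(1, 10), arms)
  expect_true(all_sig$amplified)
  expect_false(all_sig$deleted)
  miss <- call_broad_arms(chrom, pos, q_one, rep(1, 10), arms)
  expect_false(miss$amplified)
  relaxed <- call_broad_arms(chrom, pos, q_one, rep(1, 10), arms,
                             arm_fraction = 0.9)
  expect_true(relaxed$amplified)
  empty_arm <- region_annotation("chr2", 0, 1000, "2p", kind = "arms")
  expect_warning(res <- call_broad_arms(chrom, pos, q_all, q_all, empty_arm),
                 "no probes")
  expect_true(is.na(res$amplified))
})

test_that("broad pipeline flags a planted arm-scale gain", {
  set.seed(63)
  n <- 512
  vals <- matrix(rnorm(n * 8, sd = 0.1), n, 8)
  vals[1:256, ] <- vals[1:256, ] + 0.6  # first "arm" gained in all samples
  pm <- probe_matrix(rep("chr1", n), seq_len(n) * 1000L, vals)
  arms <- region_annotation(c("chr1", "chr1"), c(0, 256000),
                            c(256000, 512000), c("p", "q"), kind = "arms")
  # the coarse average blurs ~2^(J_total - L) probes at the arm boundary,
  # so on a short synthetic arm the all-probes rule is relaxed to 80%
  p <- wifa_params(C = 1, L = 4, M = 7, J_total = 9, arm_fraction = 0.8)
  br <- detect_broad(pm, p, arms = arms)
  expect_true(br$arm_calls$amplified[br$arm_calls$label == "p"])
  expect_false(br$arm_calls$amplified[br$arm_calls$label == "q"])
  expect_gt(br$arm_calls$frac_amp[1], br$arm_calls$frac_amp[2])
  expect_true(all(br$probe_calls$q_amp >= 0 & br$probe_calls$q_amp <= 1))
})
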