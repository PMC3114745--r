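test_that("summing profiles is elementwise over samples", {
  high <- cbind(a = c(0.5, 0, 0.3), b = c(-0.2, 0, 0))
  prof <- profiles_from_high(high, pos = c(1e4, 2e4, 3e4) * 1L)
  expect_equal(sum_high(prof), c(0.3, 0, 0.3))
  expect_equal(sum_high(prof$high[, 1, drop = FALSE]), high[, 1],
               ignore_attr = TRUE)
  expect_equal(sum_high(matrix(0, 4, 3)), rep(0, 4))
})

test_that("grouping, clustering, group-maximum and patient filter apply", {
  # same-sign positions at 10000, 10050, 10200 kb; d = 100 kb, gap = 1 Mb:
  # one group, two clusters; the higher-|S| cluster survives
  pos <- c(10000, 10050, 10200) * 1000
  high <- cbind(s1 = c(0.4, 0.4, 0.3), s2 = c(0.2, 0.2, 0.4))
  prof <- profiles_from_high(high, pos,
                             params = wifa_params(L = 1, M = 1, J_total = 9,
                                                  d = 1e5, group_gap = 1e6))
  cl <- build_clusters(prof)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 10000 * 1000)
  expect_equal(cl$end, 10050 * 1000)
  expect_equal(cl$score, 1.2)
  expect_equal(cl$n_patients, 2L)

  # gap exactly d joins the same cluster (inclusive comparison)
  pos2 <- c(1e6, 1e6 + 1e5)
  prof2 <- profiles_from_high(cbind(c(0.3, 0.2), c(0.1, 0.1)), pos2,
                              params = wifa_params(L = 1, M = 1, J_total = 9,
                                                   d = 1e5))
  cl2 <- build_clusters(prof2)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$score, 0.7)

  # a cluster fed by a single sample is removed
  prof3 <- profiles_from_high(cbind(c(0.9, 0.9), c(0, 0)), pos2,
                              params = wifa_params(L = 1, M = 1, J_total = 9,
                                                   d = 1e5))
  expect_equal(nrow(build_clusters(prof3)), 0L)

  # opposite signs cluster separately
  prof4 <- profiles_from_high(cbind(c(0.5, -0.5), c(0.5, -0.5)), pos2,
                              params = wifa_params(L = 1, M = 1, J_total = 9,
                                                   d = 1e5))
  cl4 <- build_clusters(prof4)
  expect_equal(sort(cl4$sign), c(-1, 1))
  # no probe is double-counted within a sign class
  for (sgn in unique(cl4$sign)) {
    members <- unlist(Map(seq, cl4$first_probe[cl4$sign == sgn],
                          cl4$last_probe[cl4$sign == sgn]))
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("segment permutation preserves the segment multiset", {
  expect_equal(permute_segments(rep(0, 10)), rep(0, 10))
  v_full <- c(1, 2, 3, 4)
  expect_equal(permute_segments(v_full), v_full)  # no free probes

  seg_sig <- function(v) {
    r <- rle(v != 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sort(vapply(which(r$values),
                function(i) paste(v[starts[i]:ends[i]], collapse = ","),
                character(1)))
  }
  set.seed(101)
  for (r in 1:100) {
    v <- rnorm(60) * rbinom(60, 1, 0.3)
    pv <- permute_segments(v)
    expect_identical(seg_sig(pv), seg_sig(v))
    expect_identical(sum(pv != 0), sum(v != 0))
    expect_identical(sort(pv[pv != 0]), sort(v[v != 0]))
  }
})

test_that("permutation p-values follow the indicator-count formula", {
  expect_equal(permutation_pvalue(2, c(5, 1, 2, 3)), 3 / 4)
  expect_equal(permutation_pvalue(-2, c(5, 1, 2, 3)), 3 / 4)  # |S| is used
  expect_equal(permutation_pvalue(10, c(5, 1, 2, 3)), 0)
  expect_equal(permutation_pvalue(0.5, c(5, 1, 2, 3)), 1)
  expect_error(permutation_pvalue(1, numeric(0)))
})

test_that("p-values decrease with |S| and land on the 1/N grid", {
  set.seed(55)
  n <- 256
  high <- matrix(rnorm(n * 4) * rbinom(n * 4, 1, 0.15), n, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  high[40:42, ] <- 1.5  # strong concordant block
  prof <- profiles_from_high(high, pos = seq_len(n) * 5e4,
                             params = wifa_params(L = 1, M = 1, J_total = 9,
                                                  d = 1e5, N = 100,
                                                  seed = 4))
  res <- detect_focal(profiles = prof)
  cl <- res$clusters
  expect_true(all(cl$p_cluster >= 0 & cl$p_cluster <= 1))
  expect_true(all(abs(cl$p_cluster * 100 - round(cl$p_cluster * 100)) <
                    1e-9))
  for (sgn in c(-1, 1)) {
    sub <- cl[cl$sign == sgn, ]
    if (nrow(sub) > 1) {
      o <- order(-abs(sub$score))
      expect_true(all(diff(sub$p_cluster[o]) >= 0))
    }
  }
  # the planted block is the top-ranked significant cluster
  expect_true(cl$significant[1])
  expect_equal(cl$rank[1], 1L)
  expect_lte(cl$start[1], 40 * 5e4)
  expect_gte(cl$end[1], 42 * 5e4)
})

test_that("focal detection is reproducible and scales linearly", {
  set.seed(12)
  cfg <- sim_config(n_markers = 512, n_samples = 12, n_concordant = 2,
                    n_nonconcordant = 1, noise_level = 0.2)
  ds <- simulate_dataset(cfg)
  p <- wifa_params(C = 1, L = 3, M = 6, N = 40, d = 1e5, seed = 31)
  r1 <- detect_focal(ds$pm, p)
  r2 <- detect_focal(ds$pm, p)
  expect_identical(r1$clusters, r2$clusters)

  # doubling every sample doubles scores and preserves order
  pm2 <- probe_matrix(ds$pm$chrom, ds$pm$pos, ds$pm$values * 2)
  prof1 <- wifa_transform(ds$pm, p)
  prof2 <- prof1
  prof2$high <- prof1$high * 2
  prof2$high_raw <- prof1$high_raw * 2
  prof2$low <- prof1$low * 2
  c1 <- build_clusters(prof1)
  c2 <- build_clusters(prof2)
  expect_near(c2$score, 2 * c1$score, 1e-12)
  expect_identical(c2$first_probe, c1$first_probe)

  # constant samples yield no clusters
  flat <- probe_matrix(rep("chr1", 64), seq_len(64) * 1000L,
                       matrix(0.3, 64, 3))
  expect_equal(nrow(detect_focal(flat, wifa_params(C = 1, L = 2, M = 4,
                                                   J_total = 6,
                                                   N = 5))$clusters), 0L)
})
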