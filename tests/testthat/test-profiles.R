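test_that("boundary sign cleanup keeps the dominant-sign members of a run", {
  # run with mixed signs; |raw| maximal at the middle probe
  y_high <- c(0, -0.3, 0.8, -0.2, 0)
  y_raw <- c(0, 0.1, 1.2, 0.1, 0)
  expect_equal(boundary_sign_cleanup(y_raw, y_high), c(0, 0, 0.8, 0, 0))

  # a run entirely of one sign is untouched
  one <- c(0, 0.2, 0.5, 0.1, 0)
  expect_equal(boundary_sign_cleanup(c(0, 1, 2, 1, 0), one), one)

  # ties on |raw| resolve to the leftmost probe
  tied <- boundary_sign_cleanup(c(1, 1), c(0.5, -0.5))
  expect_equal(tied, c(0.5, 0))

  # independent runs are processed independently
  two <- boundary_sign_cleanup(c(2, 0, 0, -2, 1), c(0.5, 0, 0, -0.4, 0.2))
  expect_equal(two, c(0.5, 0, 0, -0.4, 0))

  # surviving values equal their inputs; support shrinks
  set.seed(2)
  yh <- rnorm(50) * rbinom(50, 1, 0.4)
  yt <- boundary_sign_cleanup(rnorm(50), yh)
  nz <- yt != 0
  expect_true(all(yt[nz] == yh[nz]))
  expect_true(all(which(nz) %in% which(yh != 0)))
})

test_that("single-probe opposite-flank events are removed, wider ones kept", {
  pre <- c(-0.2, 0.9, -0.3)
  expect_equal(remove_single_probe_events(pre, c(0, 0.9, 0)), c(0, 0, 0))

  # width-2 event: the rule fires at neither positive probe
  pre2 <- c(-0.2, 0.7, 0.8, -0.3)
  til2 <- c(0, 0.7, 0.8, 0)
  expect_equal(remove_single_probe_events(pre2, til2), til2)

  expect_equal(remove_single_probe_events(rep(0, 6), rep(0, 6)), rep(0, 6))

  # chromosome ends never satisfy the two-flank condition
  pre3 <- c(0.5, -0.2, 0)
  expect_equal(remove_single_probe_events(pre3, c(0.5, 0, 0)), c(0.5, 0, 0))
})

test_that("cleanup and CNV filter are idempotent", {
  set.seed(9)
  y_raw <- rnorm(200)
  y_high <- compute_high(y_raw, 3, 0.8)
  once <- boundary_sign_cleanup(y_raw, y_high)
  expect_identical(boundary_sign_cleanup(y_raw, once), once)
  f1 <- remove_single_probe_events(y_high, once)
  expect_identical(remove_single_probe_events(y_high, f1), f1)
  # support shrinks monotonically along the pipeline
  expect_true(all(which(f1 != 0) %in% which(once != 0)))
  expect_true(all(which(once != 0) %in% which(y_high != 0)))
})

test_that("a constant sample yields zero high and constant low profiles", {
  chrom <- rep(c("chr1", "chr2"), c(40, 24))
  p <- wifa_params(L = 3, M = 5, J_total = 7)
  pr <- transform_sample(rep(0.7, 64), chrom, p)
  expect_equal(pr$high, rep(0, 64))
  expect_near(pr$low, rep(0.7, 64), 1e-9)
})

# When the 152-probe window is analysed standalone, a fine focal span
# (depth 2 = 4 probes) keeps boundary marks probe-sharp; the genome-scale
# focal span (~32 probes) only applies to full chromosomes.
fixture_params <- function(C = 1.94) wifa_params(C = C, L = 2, M = 6,
                                                 J_total = 8)

test_that("step fixture produces positive boundary marks with zero interior", {
  y <- make_step_fixture()  # 152 probes, block on 98..143
  pr <- transform_sample(y, rep("chr1", 152), fixture_params())
  nz <- which(pr$high != 0)
  expect_gt(length(nz), 0)
  expect_true(all(pr$high[nz] > 0))
  # nonzero marks sit within the focal span (4 probes) of a true boundary
  expect_true(all(pmin(abs(nz - 98), abs(nz - 143)) <= 4))
  # deep interior and far exterior are exactly zero in the noiseless case
  expect_true(all(pr$high[c(1:92, 104:138, 148:152)] == 0))
})

test_that("boundary probes dominate the noisy step fixture", {
  # C from the method's own recipe: calibrate to ~10% nonzero values
  set.seed(123)
  y0 <- make_step_fixture() + rnorm(152, sd = 0.1)
  pmx <- probe_matrix(rep("chr1", 152), seq_len(152) * 50000L,
                      matrix(y0, ncol = 1))
  C <- suppressWarnings(calibrate_C(pmx, fixture_params(), 0.10))
  p <- fixture_params(C)
  hits <- 0L
  set.seed(123)
  for (r in 1:100) {
    y <- make_step_fixture() + rnorm(152, sd = 0.1)
    pr <- transform_sample(y, rep("chr1", 152), p)
    top2 <- order(abs(pr$high), decreasing = TRUE)[1:2]
    if (setequal(top2, c(98L, 143L))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("sample transform commutes with rotation on dyadic input", {
  set.seed(77)
  y <- rnorm(64) + rep(c(0, 1.2, 0, 0), each = 16)
  p <- wifa_params(C = 1, L = 2, M = 4, J_total = 6, cnv_filter = FALSE)
  rot <- function(v, k) v[((seq_along(v) - 1 + k) %% length(v)) + 1]
  base <- transform_sample(y, rep("chr1", 64), p)$high_raw
  for (k in c(3, 17)) {
    shifted <- transform_sample(rot(y, k), rep("chr1", 64), p)$high_raw
    expect_near(shifted, rot(base, k), 1e-10)
  }
})

test_that("short chromosomes yield zero profiles with a warning", {
  p <- wifa_params(L = 2, M = 3, J_total = 6)
  expect_warning(
    pr <- transform_sample(c(rnorm(32), 0.5), rep(c("chr1", "chr2"),
                                                  c(32, 1)), p),
    "< 2 probes")
  expect_equal(pr$high[33], 0)
  expect_equal(pr$low[33], 0)
})
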