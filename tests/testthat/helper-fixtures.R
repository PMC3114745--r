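# Shared fixture builders (all data generated in code).

# small probe matrix on two chromosomes with evenly spaced probes
toy_pm <- function(n1 = 8L, n2 = 6L, n_samples = 2L, spacing = 1e5,
                   seed = 1L) {
  set.seed(seed)
  n <- n1 + n2
  probe_matrix(chrom = rep(c("chr1", "chr2"), c(n1, n2)),
               pos = as.integer(c(seq_len(n1), seq_len(n2)) * spacing),
               values = matrix(rnorm(n * n_samples), n, n_samples),
               sample_ids = paste0("s", seq_len(n_samples)))
}

# wifa_profiles object built directly from a matrix of post-processed
# high-frequency values (for clustering tests that control inputs exactly)
profiles_from_high <- function(high, pos, chrom = rep("chr1", nrow(high)),
                               params = wifa_params(L = 1, M = 1,
                                                    J_total = 99)) {
  params$J_total <- NULL  # not used downstream of the transform
  structure(list(high = high, high_raw = high,
                 low = matrix(0, nrow(high), ncol(high)),
                 chrom = chrom, pos = pos,
                 sample_ids = colnames(high), params = params),
            class = "wifa_profiles")
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)), tol)
}
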