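#' Zero opposite-sign flanks within runs of nonzero high-frequency values
#'
#' High-frequency Haar reconstructions of an amplification flank its positive
#' boundary values with negative ones (positions next to an aberration also
#' differ strongly from their neighbours), and vice versa for deletions. For
#' each maximal run of consecutive probes with nonzero `y_high`, the run
#' member with the largest `|y_raw|` (ties: leftmost) defines the run's sign;
#' members whose `y_high` sign differs are set to zero. Idempotent; every
#' surviving value equals its `y_high` input.
#'
#' @param y_raw Observed log2 ratios, aligned to `y_high`.
#' @param y_high High-frequency profile from [compute_high()].
#' @return Cleaned profile (same length).
#' @export
boundary_sign_cleanup <- function(y_raw, y_high) {
  stopifnot(length(y_raw) == length(y_high))
  out <- y_high
  r <- rle(y_high != 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    run <- starts[i]:ends[i]
    anchor <- run[which.max(abs(y_raw[run]))]
    s <- sign(y_high[anchor])
    out[run][sign(y_high[run]) != s] <- 0
  }
  out
}

#' Remove single-probe aberration signatures (germline CNV filter)
#'
#' Width-one events in the high-frequency profile - a probe whose value is
#' flanked on both sides (within `k` probes, in the pre-cleanup profile) by
#' nonzero values of the opposite sign - typically reflect germline copy
#' number variants segregating in the normal population rather than somatic
#' aberrations, and are zeroed. True focal boundaries are untouched because
#' one of their flanks lies inside the aberration. Idempotent.
#'
#' @param y_high_pre High-frequency profile before [boundary_sign_cleanup()].
#' @param y_tilde Profile after cleanup, aligned to `y_high_pre`.
#' @param k Flank window in probes (default 1).
#' @return Filtered profile.
#' @export
remove_single_probe_events <- function(y_high_pre, y_tilde, k = 1L) {
  stopifnot(length(y_high_pre) == length(y_tilde), k >= 1L)
  n <- length(y_tilde)
  out <- y_tilde
  for (p in which(y_tilde != 0)) {
    s <- sign(y_high_pre[p])
    if (s == 0 || p == 1L || p == n) next
    left <- max(1L, p - k):(p - 1L)
    right <- (p + 1L):min(n, p + k)
    left_opp <- any(sign(y_high_pre[left]) == -s)
    right_opp <- any(sign(y_high_pre[right]) == -s)
    if (left_opp && right_opp) out[p] <- 0
  }
  out
}

#' High- and low-frequency profiles of one sample
#'
#' Runs the full per-sample decomposition, chromosome by chromosome: extend
#' to dyadic length, synthesise the thresholded high-frequency profile
#' (depth `J_total - M`) and the unthresholded low-frequency profile (depth
#' `J_total - L`), restrict to the original probes, then apply
#' [boundary_sign_cleanup()] and (optionally) [remove_single_probe_events()].
#' Depths exceeding a short chromosome's capacity are clipped with a warning.
#'
#' @param y Numeric vector: one sample's log2 ratios, probe-aligned.
#' @param chrom Chromosome label per probe.
#' @param params A [wifa_params()] with `L`, `M`, `J_total` resolved.
#' @return List with probe-aligned vectors `high` (post-processed),
#'   `high_raw` (before post-processing) and `low`.
#' @export
transform_sample <- function(y, chrom, params) {
  stopifnot(length(y) == length(chrom))
  params <- resolve_params(params, length(y))
  D_high0 <- depth_from_level(params$M, params$J_total)
  D_low0 <- depth_from_level(params$L, params$J_total)
  high <- high_raw <- low <- numeric(length(y))
  for (ix in chrom_indices(list(chrom = chrom))) {
    v <- y[ix]
    if (length(v) < 2L) {
      warning("chromosome with < 2 probes: profiles set to zero")
      next
    }
    sig <- extend_to_dyadic(v)
    yh <- compute_high(sig, clip_depth(D_high0, sig$Jc, warn = TRUE),
                       params$C)
    yl <- compute_low(sig, clip_depth(D_low0, sig$Jc, warn = TRUE))
    yt <- boundary_sign_cleanup(v, yh)
    if (params$cnv_filter)
      yt <- remove_single_probe_events(yh, yt, params$cnv_k)
    high_raw[ix] <- yh
    high[ix] <- yt
    low[ix] <- yl
  }
  list(high = high, high_raw = high_raw, low = low)
}

#' Profiles for every sample of a probe matrix
#'
#' @param pm A [probe_matrix()].
#' @param params A [wifa_params()]; `J_total` is filled from the data when
#'   `NULL`.
#' @return A `wifa_profiles` object: list with matrices `high`, `high_raw`,
#'   `low` (probes x samples) plus the probe grid (`chrom`, `pos`,
#'   `sample_ids`) and the resolved `params`.
#' @export
wifa_transform <- function(pm, params) {
  stopifnot(inherits(pm, "probe_matrix"))
  params <- resolve_params(params, length(pm$pos))
  ns <- ncol(pm$values)
  high <- high_raw <- low <-
    matrix(0, length(pm$pos), ns, dimnames = list(NULL, pm$sample_ids))
  for (j in seq_len(ns)) {
    pr <- transform_sample(pm$values[, j], pm$chrom, params)
    high[, j] <- pr$high
    high_raw[, j] <- pr$high_raw
    low[, j] <- pr$low
  }
  structure(list(high = high, high_raw = high_raw, low = low,
                 chrom = pm$chrom, pos = pm$pos,
                 sample_ids = pm$sample_ids, params = params),
            class = "wifa_profiles")
}
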