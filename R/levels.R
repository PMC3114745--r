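# Reference platform: 100K SNP array, ~50 kb between probes, J_total = 17,
# L = 9 (averaging span 2^(17-9) x 50 kb = 12,800 kb) and M = 12 (focal span
# 2^(17-12) x 50 kb = 1,600 kb). Level transfer to another platform keeps
# these physical spans fixed.
.ref_low_span_bp <- 2^(17 - 9) * 50e3
.ref_high_span_bp <- 2^(17 - 12) * 50e3

# round to nearest; exact halves round down (the finer level wins)
round_half_down <- function(x) ceiling(x - 0.5)

#' Transfer wavelet levels to a new array platform
#'
#' Picks the coarse level `L` and fine level `M` for a platform with a given
#' average probe spacing so that the physical spans of the low-frequency
#' average (12.8 Mb) and of the focal high-frequency window (1.6 Mb) match
#' the reference 100K-array configuration (50 kb spacing, `J_total = 17`,
#' `L = 9`, `M = 12`):
#' `L = J_total - round(log2(12.8e6 / spacing))` and
#' `M = J_total - round(log2(1.6e6 / spacing))`, clipped into
#' `[1, J_total - 1]` with `L <= M`.
#'
#' @param spacing Average distance between probes in base pairs (> 0).
#' @param J_total `ceiling(log2(total probe count))` of the data set.
#' @return Named integer vector `c(L = , M = )`.
#' @examples
#' choose_levels(50e3, 17)  # reference: L = 9, M = 12
#' choose_levels(13e3, 18)  # 250K-style array: L = 8, M = 11
#' @export
choose_levels <- function(spacing, J_total) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  J_total <- as.integer(J_total)
  stopifnot(J_total >= 2L)
  L <- J_total - round_half_down(log2(.ref_low_span_bp / spacing))
  M <- J_total - round_half_down(log2(.ref_high_span_bp / spacing))
  L <- min(max(L, 1L), J_total - 1L)
  M <- min(max(M, 1L), J_total - 1L)
  if (L > M) L <- M
  c(L = as.integer(L), M = as.integer(M))
}

# fraction of probe values (all samples, all chromosomes) with nonzero y_HIGH
high_nonzero_fraction <- function(pm, params, C) {
  idx <- chrom_indices(pm)
  D_high <- depth_from_level(params$M, params$J_total)
  nz <- 0L
  for (ix in idx) {
    if (length(ix) < 2L) next
    for (j in seq_len(ncol(pm$values))) {
      sig <- extend_to_dyadic(pm$values[ix, j])
      d <- clip_depth(D_high, sig$Jc)
      nz <- nz + sum(compute_high(sig, d, C) != 0)
    }
  }
  nz / (length(pm$pos) * ncol(pm$values))
}

#' Calibrate the threshold multiplier to a nonzero-fraction target
#'
#' Bisects on `C` until the fraction of probes (over all samples and
#' chromosomes) with nonzero high-frequency values is within +/- 0.5
#' percentage points of `target_fraction`. The fraction is non-increasing in
#' `C` (hard-threshold monotonicity); because it is a step function the
#' target may be unattainable, in which case the lower bracket endpoint is
#' returned with a warning.
#'
#' @param pm A [probe_matrix()] of log2 ratios.
#' @param params A [wifa_params()] with `M` and `J_total` set (`J_total` is
#'   filled from the data if `NULL`).
#' @param target_fraction Desired fraction in (0, 1); the reference analyses
#'   use 0.10.
#' @param tol Acceptable absolute deviation from the target (default 0.005).
#' @param max_iter Bisection iteration cap.
#' @return The calibrated scalar `C`.
#' @export
calibrate_C <- function(pm, params, target_fraction = 0.10, tol = 0.005,
                        max_iter = 50L) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  params <- resolve_params(params, length(pm$pos))
  lo <- 0
  hi <- 1
  f_hi <- high_nonzero_fraction(pm, params, hi)
  while (f_hi > target_fraction && hi < 2^16) {
    lo <- hi
    hi <- hi * 2
    f_hi <- high_nonzero_fraction(pm, params, hi)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- high_nonzero_fraction(pm, params, mid)
    if (abs(f - target_fraction) <= tol) return(mid)
    if (f > target_fraction) lo <- mid else hi <- mid
  }
  warning(sprintf(
    "calibrate_C: target %.3f not attained (bracket [%.4g, %.4g]); %s",
    target_fraction, lo, hi, "returning lower bracket endpoint"))
  lo
}

# L/M are counted against J_total; per-chromosome transforms use depths from
# the fine end, which are chromosome-independent.
depth_from_level <- function(level, J_total) {
  as.integer(J_total - level)
}

clip_depth <- function(depth, Jc, warn = FALSE) {
  d <- max(1L, min(as.integer(depth), Jc - 1L, Jc))
  if (warn && d != depth)
    warning("transform depth clipped from ", depth, " to ", d,
            " on a short chromosome")
  d
}
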