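# Broad (arm-scale) aberrations: the summed low-frequency profile is compared
# probe-wise against the exact null distribution of a sum of independent
# draws, one per sample, from each sample's own genome-wide histogram of
# low-frequency values. The null is computed by discrete convolution of the
# per-sample histograms on a shared bin grid.

# integer bin index of a value on the grid of centers k * bin_width
bin_index <- function(x, bin_width) as.integer(round(x / bin_width))

#' Histogram-convolution null for summed low-frequency values
#'
#' Each sample's genome-wide low-frequency values are binned to the nearest
#' centre of a uniform grid (width `bin_width`, centres at integer multiples
#' of it); the null distribution of the per-probe sum across samples under
#' independence is the iterated discrete convolution of these histograms,
#' renormalised after every pairwise convolution to control floating-point
#' drift.
#'
#' @param low Probes x samples matrix of low-frequency values, or a
#'   `wifa_profiles` object.
#' @param bin_width Bin width on the log2-ratio scale (default 0.01).
#' @return A `wifa_null` object: list with `offset` (integer index of the
#'   first bin), `mass` (probabilities summing to 1) and `bin_width`. Bin `i`
#'   has centre `(offset + i - 1) * bin_width`.
#' @export
build_null <- function(low, bin_width = 0.01) {
  if (inherits(low, "wifa_profiles")) low <- low$low
  stopifnot(is.matrix(low), ncol(low) >= 1L, bin_width > 0)
  if (!all(is.finite(low))) stop("low-frequency values must be finite")
  off <- 0L
  mass <- 1
  for (j in seq_len(ncol(low))) {
    k <- bin_index(low[, j], bin_width)
    h_off <- min(k)
    h <- tabulate(k - h_off + 1L, max(k) - h_off + 1L)
    h <- h / sum(h)
    mass <- convolve_mass(mass, h)
    off <- off + h_off
    mass <- mass / sum(mass)
  }
  mass[mass < 0] <- 0
  structure(list(offset = off, mass = mass / sum(mass),
                 bin_width = bin_width),
            class = "wifa_null")
}

# full (open) discrete convolution of two probability mass vectors
convolve_mass <- function(a, b) {
  if (length(a) == 1L) return(a[1L] * b)
  if (length(b) == 1L) return(b[1L] * a)
  stats::convolve(a, rev(b), type = "open")
}

#' Tail p-values of observed summed low-frequency values
#'
#' The observed statistic at a probe is the sum of per-sample low-frequency
#' values. It is binned on the null's grid and its amplification p-value is
#' the null mass at or above the observed bin (`P(X >= obs)`), the deletion
#' p-value the mass at or below it; the observed bin is included in both
#' tails (conservative). Values beyond the grid get the mass beyond that end
#' (0), with a warning.
#'
#' @param observed Numeric vector of per-probe summed low-frequency values
#'   (e.g. `rowSums(profiles$low)`).
#' @param null A `wifa_null` from [build_null()].
#' @return Data frame with columns `p_amp` and `p_del`.
#' @export
broad_pvalues <- function(observed, null) {
  stopifnot(inherits(null, "wifa_null"))
  k <- bin_index(observed, null$bin_width) - null$offset + 1L
  nb <- length(null$mass)
  if (any(k < 1L | k > nb))
    warning("observed value(s) outside the null grid; tail mass is 0 there")
  upper <- rev(cumsum(rev(null$mass)))   # P(X >= bin i)
  lower <- cumsum(null$mass)             # P(X <= bin i)
  ki <- pmin(pmax(k, 1L), nb)            # clamped index for lookup
  p_amp <- ifelse(k > nb, 0, upper[ki])
  p_del <- ifelse(k < 1L, 0, lower[ki])
  data.frame(p_amp = pmin(p_amp, 1), p_del = pmin(p_del, 1))
}

#' Storey q-values
#'
#' Converts p-values to q-values with the fixed-lambda (0.5) estimate of the
#' null proportion, `pi0 = #\{p > 0.5\} / (0.5 * m)` capped at 1: the q-value
#' of the i-th ordered p-value is `min over j >= i of pi0 * m * p_(j) / j`,
#' capped at 1. Ties keep input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion; estimated from `p` when `NULL`.
#' @return Numeric vector of q-values, aligned to `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(pi0)) pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  o <- order(p)
  qs <- pi0 * m * p[o] / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

#' Call chromosome arms as broadly aberrant
#'
#' An arm is flagged amplified (deleted) when the fraction of its probes with
#' `q_amp < q_threshold` (`q_del < q_threshold`) reaches `arm_fraction`
#' (default 1: every probe significant). Arms without probes are left
#' uncalled with a warning.
#'
#' @param chrom,pos Probe grid (1-based bp).
#' @param q_amp,q_del Per-probe q-values.
#' @param arms A [region_annotation()] of chromosome arms.
#' @param q_threshold Significance cutoff (default 0.01).
#' @param arm_fraction Required fraction of significant probes (default 1).
#' @return Data frame: one row per arm with `n_probes`, `frac_amp`,
#'   `frac_del`, `amplified`, `deleted`.
#' @export
call_broad_arms <- function(chrom, pos, q_amp, q_del, arms,
                            q_threshold = 0.01, arm_fraction = 1.0) {
  stopifnot(nrow(arms) >= 1L)
  res <- arms[, c("chrom", "start", "end", "label")]
  res$n_probes <- 0L
  res$frac_amp <- res$frac_del <- NA_real_
  res$amplified <- res$deleted <- NA
  for (i in seq_len(nrow(arms))) {
    in_arm <- chrom == arms$chrom[i] &
      pos > arms$start[i] & pos <= arms$end[i]
    n <- sum(in_arm)
    res$n_probes[i] <- n
    if (n == 0L) {
      warning("arm ", arms$label[i], " on ", arms$chrom[i], " has no probes")
      next
    }
    res$frac_amp[i] <- mean(q_amp[in_arm] < q_threshold)
    res$frac_del[i] <- mean(q_del[in_arm] < q_threshold)
    res$amplified[i] <- res$frac_amp[i] >= arm_fraction
    res$deleted[i] <- res$frac_del[i] >= arm_fraction
  }
  res
}

#' Detect broad (arm-scale) copy-number aberrations
#'
#' Full broad pipeline: per-sample low-frequency profiles, histogram
#' convolution null, per-probe amplification/deletion tail p-values, Storey
#' q-values, and (when arm definitions are supplied) arm-level calls.
#'
#' @param pm A [probe_matrix()]; ignored when `profiles` is supplied.
#' @param params A [wifa_params()].
#' @param arms Optional [region_annotation()] of chromosome arms.
#' @param profiles Optional precomputed `wifa_profiles`.
#' @return A `wifa_broad` object: list with `probe_calls` (per-probe data
#'   frame: observed sum, p- and q-values), `arm_calls` (or `NULL`), `null`
#'   and `params`.
#' @export
detect_broad <- function(pm, params = wifa_params(), arms = NULL,
                         profiles = NULL) {
  if (is.null(profiles)) {
    stopifnot(inherits(pm, "probe_matrix"))
    params <- resolve_params(params, length(pm$pos))
    profiles <- wifa_transform(pm, params)
  }
  params <- profiles$params
  null <- build_null(profiles$low, params$bin_width)
  obs <- rowSums(profiles$low)
  pv <- broad_pvalues(obs, null)
  probe_calls <- data.frame(chrom = profiles$chrom, pos = profiles$pos,
                            low_sum = obs, p_amp = pv$p_amp,
                            p_del = pv$p_del,
                            q_amp = qvalues(pv$p_amp),
                            q_del = qvalues(pv$p_del),
                            stringsAsFactors = FALSE)
  arm_calls <- if (!is.null(arms))
    call_broad_arms(profiles$chrom, profiles$pos, probe_calls$q_amp,
                    probe_calls$q_del, arms, params$q_threshold,
                    params$arm_fraction)
  structure(list(probe_calls = probe_calls, arm_calls = arm_calls,
                 null = null, params = params),
            class = "wifa_broad")
}

#' @export
print.wifa_broad <- function(x, ...) {
  cat(sprintf("wifa_broad: %d probes; %d probe(s) with q_amp < %g, %d with q_del < %g\n",
              nrow(x$probe_calls),
              sum(x$probe_calls$q_amp < x$params$q_threshold),
              x$params$q_threshold,
              sum(x$probe_calls$q_del < x$params$q_threshold),
              x$params$q_threshold))
  if (!is.null(x$arm_calls)) {
    amp <- x$arm_calls$label[isTRUE_vec(x$arm_calls$amplified)]
    del <- x$arm_calls$label[isTRUE_vec(x$arm_calls$deleted)]
    cat("  amplified arms:", if (length(amp)) paste(amp, collapse = ", ")
        else "none", "\n")
    cat("  deleted arms:  ", if (length(del)) paste(del, collapse = ", ")
        else "none", "\n")
  }
  invisible(x)
}

isTRUE_vec <- function(x) !is.na(x) & x
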