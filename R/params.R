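#' Analysis parameters
#'
#' Bundles every tunable of the focal/broad aberration pipeline. `L` and `M`
#' are coarse/fine level indices counted against `J_total = ceiling(log2(n))`
#' for the whole data set: the low-frequency profile keeps scaling content at
#' level `L` (depth `J_total - L` from the finest scale) and the
#' high-frequency profile keeps thresholded detail at levels `M .. J_total-1`
#' (depths `1 .. J_total - M`). Smaller `M` admits more nonzero
#' high-frequency values.
#'
#' @param C Hard-threshold multiplier (dimensionless, >= 0). The per-level
#'   threshold is `C * sigma_j * sqrt(2 * log(n_j))`.
#' @param L Coarse level index, `1 <= L <= M`.
#' @param M Fine level index, `L <= M <= J_total - 1`.
#' @param J_total `ceiling(log2(total probe count))`; computed from the data
#'   when `NULL`.
#' @param group_gap Maximum base-pair gap between consecutive same-sign
#'   nonzero positions within a group (default 1 Mb).
#' @param d Maximum base-pair gap between consecutive positions within a
#'   cluster (default 100 kb); must satisfy `d <= group_gap`.
#' @param N Number of permutations for the cluster null (default 1000).
#' @param alpha Significance level for cluster p-values (default 0.1).
#' @param bin_width Histogram bin width on the log2-ratio scale for the
#'   broad-aberration convolution null (default 0.01).
#' @param q_threshold q-value cutoff for per-probe broad significance
#'   (default 0.01).
#' @param arm_fraction Fraction of an arm's probes that must be significant
#'   before the arm is called broadly aberrant (default 1.0 = all probes).
#' @param cnv_k Flank window (in probes) for the single-probe germline-CNV
#'   filter (default 1); see [remove_single_probe_events()].
#' @param cnv_filter Apply the single-probe CNV filter (default `TRUE`).
#' @param seed Integer seed making permutation p-values reproducible.
#' @return An object of class `wifa_params` (a validated list).
#' @examples
#' wifa_params(C = 1.94, L = 9, M = 12, J_total = 17)
#' @export
wifa_params <- function(C = 1.94, L = NULL, M = NULL, J_total = NULL,
                        group_gap = 1e6, d = 1e5, N = 1000, alpha = 0.1,
                        bin_width = 0.01, q_threshold = 0.01,
                        arm_fraction = 1.0, cnv_k = 1L, cnv_filter = TRUE,
                        seed = NULL) {
  stopifnot(is.numeric(C), length(C) == 1L, C >= 0,
            is.numeric(group_gap), group_gap > 0,
            is.numeric(d), d > 0, d <= group_gap,
            is.numeric(N), N >= 1,
            is.numeric(alpha), alpha > 0, alpha <= 1,
            is.numeric(bin_width), bin_width > 0,
            is.numeric(q_threshold), q_threshold > 0, q_threshold <= 1,
            is.numeric(arm_fraction), arm_fraction > 0, arm_fraction <= 1,
            is.numeric(cnv_k), cnv_k >= 1,
            is.logical(cnv_filter))
  p <- structure(
    list(C = as.numeric(C), L = L, M = M, J_total = J_total,
         group_gap = as.numeric(group_gap), d = as.numeric(d),
         N = as.integer(N), alpha = as.numeric(alpha),
         bin_width = as.numeric(bin_width),
         q_threshold = as.numeric(q_threshold),
         arm_fraction = as.numeric(arm_fraction),
         cnv_k = as.integer(cnv_k), cnv_filter = isTRUE(cnv_filter),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "wifa_params")
  validate_levels(p)
  p
}

validate_levels <- function(p) {
  if (!is.null(p$L) && !is.null(p$M)) {
    stopifnot(p$L >= 1, p$L <= p$M)
    if (!is.null(p$J_total)) stopifnot(p$M <= p$J_total - 1)
  }
  invisible(p)
}

#' @export
print.wifa_params <- function(x, ...) {
  cat("wifa_params:\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-13s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

# Fill L/M/J_total from the data if absent; transforms are run per chromosome
# at depths counted from the fine end, which are chromosome-independent.
resolve_params <- function(params, n_probes) {
  if (is.null(params$J_total))
    params$J_total <- max(1L, as.integer(ceiling(log2(n_probes))))
  if (is.null(params$L) || is.null(params$M))
    stop("params$L and params$M must be set (see choose_levels())")
  validate_levels(params)
  params
}
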