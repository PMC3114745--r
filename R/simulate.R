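#' Configuration for the synthetic multi-sample benchmark
#'
#' Emulates the published benchmark design for multi-sample aberration
#' callers: a 4,500-marker genome, 50 samples, 30-marker concordant
#' aberrations carried by 50-70% of samples, five to seven concordant
#' regions plus one or two single-carrier (nonconcordant) regions, and
#' Gaussian background noise whose per-sample standard deviation is
#' `noise_level` times that sample's maximum absolute true value.
#'
#' @param n_markers Markers per genome (default 4500; one chromosome).
#' @param n_samples Number of samples (default 50).
#' @param aberration_width Width of every aberration in markers (default 30).
#' @param freq_range Carrier-fraction range for concordant regions
#'   (default `c(0.5, 0.7)`).
#' @param n_concordant Number of concordant regions; `NULL` (default) draws
#'   uniformly from 5:7 per data set.
#' @param n_nonconcordant Number of single-carrier regions; `NULL` draws from
#'   1:2.
#' @param amplitude Absolute aberration height in log2 units (default 1.0;
#'   each region gets a random sign).
#' @param noise_level Noise multiplier (benchmark values: 0.2 and 0.4).
#' @param spacing Marker spacing in bp (default 50 kb, the 100K-array
#'   density, so the platform level-transfer rule applies directly).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_markers = 4500L, n_samples = 50L,
                       aberration_width = 30L, freq_range = c(0.5, 0.7),
                       n_concordant = NULL, n_nonconcordant = NULL,
                       amplitude = 1.0, noise_level = 0.2,
                       spacing = 50e3) {
  stopifnot(n_markers >= 1L, n_samples >= 1L, aberration_width >= 1L,
            length(freq_range) == 2L, all(freq_range > 0),
            all(freq_range <= 1), freq_range[1] <= freq_range[2],
            amplitude >= 0, noise_level >= 0, spacing > 0)
  structure(list(n_markers = as.integer(n_markers),
                 n_samples = as.integer(n_samples),
                 aberration_width = as.integer(aberration_width),
                 freq_range = as.numeric(freq_range),
                 n_concordant = n_concordant,
                 n_nonconcordant = n_nonconcordant,
                 amplitude = as.numeric(amplitude),
                 noise_level = as.numeric(noise_level),
                 spacing = as.numeric(spacing)),
            class = "sim_config")
}

# non-overlapping 1-based start positions for `count` regions of `width`
place_regions <- function(count, width, n_markers, max_tries = 1000L) {
  if (count == 0L) return(integer())
  if (count * width > n_markers)
    stop("regions cannot be placed without overlap")
  for (t in seq_len(max_tries)) {
    starts <- sort(sample.int(n_markers - width + 1L, count))
    if (count == 1L || all(diff(starts) >= width)) return(starts)
  }
  stop("could not place non-overlapping regions after ", max_tries, " tries")
}

#' Simulate a multi-sample benchmark data set
#'
#' Places the concordant and nonconcordant regions without overlap, assigns
#' each concordant region a carrier fraction drawn uniformly from
#' `freq_range` and a random carrier subset, gives carriers `+/- amplitude`
#' over the region, and adds Gaussian noise with per-sample standard
#' deviation `noise_level * max |true value of that sample|` (samples with an
#' all-zero truth use `noise_level * amplitude`). Uses R's global RNG; call
#' `set.seed()` first for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `truth` and `observed`
#'   (markers x samples matrices), `mask` (1 for markers inside a concordant
#'   region), `regions` (data frame: start/end marker, sign, concordant flag,
#'   carrier count), and `pm` (the observed data as a [probe_matrix()] on a
#'   single chromosome with `config$spacing` between markers).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nc <- if (is.null(config$n_concordant)) sample(5:7, 1L) else
    as.integer(config$n_concordant)
  nn <- if (is.null(config$n_nonconcordant)) sample(1:2, 1L) else
    as.integer(config$n_nonconcordant)
  w <- config$aberration_width
  nm <- config$n_markers
  ns <- config$n_samples
  starts <- place_regions(nc + nn, w, nm)
  concordant <- rep(c(TRUE, FALSE), c(nc, nn))[sample.int(nc + nn)]
  truth <- matrix(0, nm, ns)
  mask <- integer(nm)
  regions <- vector("list", nc + nn)
  for (i in seq_along(starts)) {
    span <- starts[i]:(starts[i] + w - 1L)
    sgn <- sample(c(-1, 1), 1L)
    if (concordant[i]) {
      frac <- stats::runif(1L, config$freq_range[1], config$freq_range[2])
      carriers <- sample.int(ns, max(1L, round(frac * ns)))
      mask[span] <- 1L
    } else {
      carriers <- sample.int(ns, 1L)
    }
    truth[span, carriers] <- truth[span, carriers] + sgn * config$amplitude
    regions[[i]] <- data.frame(start = starts[i], end = starts[i] + w - 1L,
                               sign = sgn, concordant = concordant[i],
                               n_carriers = length(carriers))
  }
  ds <- structure(list(truth = truth, observed = truth, mask = mask,
                       regions = do.call(rbind, regions), pm = NULL,
                       config = config),
                  class = "sim_dataset")
  with_noise(ds, config$noise_level)
}

#' Re-observe a simulated truth under a new noise level
#'
#' The benchmark separates truth generation from noise: the same underlying
#' true data can be observed at several noise levels. Regenerates `observed`
#' (and the embedded probe matrix) from `ds$truth` with per-sample standard
#' deviation `noise_level * max |true|` (all-zero samples use
#' `noise_level * amplitude`), leaving the truth, mask and regions untouched.
#' Uses R's global RNG.
#'
#' @param ds A `sim_dataset` from [simulate_dataset()].
#' @param noise_level Noise multiplier.
#' @return A `sim_dataset` with new `observed`, `pm` and `config$noise_level`.
#' @export
with_noise <- function(ds, noise_level) {
  stopifnot(inherits(ds, "sim_dataset"), noise_level >= 0)
  cfg <- ds$config
  cfg$noise_level <- as.numeric(noise_level)
  nm <- nrow(ds$truth)
  ns <- ncol(ds$truth)
  sd_j <- apply(ds$truth, 2L, function(col) {
    m <- max(abs(col))
    noise_level * if (m > 0) m else cfg$amplitude
  })
  observed <- ds$truth + matrix(stats::rnorm(nm * ns), nm, ns) %*% diag(sd_j, ns)
  ds$observed <- observed
  ds$pm <- probe_matrix(rep("chr1", nm), as.integer(seq_len(nm) * cfg$spacing),
                        observed, paste0("sample", seq_len(ns)))
  ds$config <- cfg
  ds
}

#' Single-sample step fixture
#'
#' A noiseless profile of `n` markers that is zero except for a constant
#' block: the canonical picture of one strong amplification used to
#' illustrate how the high-frequency transform marks aberration boundaries.
#' Defaults reproduce a 152-probe window with an amplification spanning
#' probes 98-143.
#'
#' @param n Number of markers (default 152).
#' @param start,end 1-based inclusive bounds of the block (defaults 98, 143).
#' @param height Block height in log2 units (default 1).
#' @return Numeric vector of length `n`.
#' @export
make_step_fixture <- function(n = 152L, start = 98L, end = 143L,
                              height = 1.0) {
  n <- as.integer(n); start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start || end > n)
    stop("need 1 <= start <= end <= n")
  v <- numeric(n)
  v[start:end] <- height
  v
}

#' Area under the sensitivity / false-positive-rate curve
#'
#' Rank-sum (Mann-Whitney) AUC with ties averaged; identical to trapezoidal
#' integration of the ROC curve over all thresholds of `scores`.
#'
#' @param scores Per-marker detection statistic (higher = more aberrant).
#' @param truth_mask 0/1 (or logical) vector marking truly aberrant markers.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, truth_mask) {
  truth_mask <- as.logical(truth_mask)
  stopifnot(length(scores) == length(truth_mask))
  n1 <- sum(truth_mask)
  n0 <- sum(!truth_mask)
  if (n1 == 0L || n0 == 0L)
    stop("truth mask must contain both classes")
  r <- rank(scores)
  (sum(r[truth_mask]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
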