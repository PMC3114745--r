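#' Extend a signal to dyadic length
#'
#' Chromosomes rarely have 2^J probes, so each chromosome signal is extended
#' first symmetrically (reflected) and then periodically: the extension is
#' the first `2^Jc` entries of the infinite periodic tiling of
#' `c(values, rev(values))`, with `Jc = ceiling(log2(n))` (minimum 1).
#' Restricting the extension to its first `n` entries reproduces the input.
#'
#' @param values Numeric vector, length >= 1.
#' @return A `dyadic_signal`: list with `extended` (length `2^Jc`), the
#'   original length `n_orig`, and `Jc`. Original probes occupy positions
#'   `1..n_orig`.
#' @examples
#' extend_to_dyadic(c(1, 2, 3))$extended  # 1 2 3 3
#' @export
extend_to_dyadic <- function(values) {
  n <- length(values)
  if (n == 0L) stop("cannot extend an empty signal")
  if (!all(is.finite(values))) stop("signal values must be finite")
  Jc <- max(1L, as.integer(ceiling(log2(n))))
  len <- 2L^Jc
  tile <- c(values, rev(values))
  ext <- tile[((seq_len(len) - 1L) %% length(tile)) + 1L]
  structure(list(extended = as.numeric(ext), n_orig = n, Jc = Jc),
            class = "dyadic_signal")
}

as_dyadic <- function(x) {
  if (inherits(x, "dyadic_signal")) x else extend_to_dyadic(x)
}

#' Stationary Haar wavelet analysis
#'
#' Orthonormal a-trous Haar transform with circular boundary. Depth-1 detail
#' at position t is `(x[t] - x[t + 1 mod n]) / sqrt(2)`; deeper depths apply
#' the same filter pair, dilated by 2 per depth, to the running
#' approximation. All coefficient vectors keep the full redundant length
#' `2^Jc`; the transform is shift-equivariant, and synthesis by
#' [haar_iswt()] equals the average over all circular shifts of the
#' corresponding decimated transforms.
#'
#' @param signal A `dyadic_signal` (or numeric vector, extended on the fly).
#' @param depth Decomposition depth `D`, `1 <= D <= Jc`.
#' @return An `swt_coefficients` object: list with `approx` (depth-D scaling
#'   coefficients), `details` (list of length D, fine to coarse), `depth`,
#'   `Jc`, `n_orig`.
#' @export
haar_swt <- function(signal, depth) {
  sig <- as_dyadic(signal)
  n <- length(sig$extended)
  depth <- as.integer(depth)
  if (depth < 1L || depth > sig$Jc)
    stop("depth must be in 1..Jc (= ", sig$Jc, ")")
  a <- sig$extended
  details <- vector("list", depth)
  idx <- seq_len(n) - 1L
  for (k in seq_len(depth)) {
    s <- 2L^(k - 1L)
    a_sh <- a[((idx + s) %% n) + 1L]
    details[[k]] <- (a - a_sh) / sqrt(2)
    a <- (a + a_sh) / sqrt(2)
  }
  structure(list(approx = a, details = details, depth = depth,
                 Jc = sig$Jc, n_orig = sig$n_orig),
            class = "swt_coefficients")
}

#' Stationary Haar wavelet synthesis
#'
#' Inverse of [haar_swt()]: at every depth the two redundant single-shift
#' reconstructions are averaged, which makes the round trip exact and the
#' synthesis equal to cycle spinning (the average over all circular shifts of
#' inverse decimated Haar transforms). Linear in the coefficients.
#'
#' @param coeffs An `swt_coefficients` object (possibly with modified
#'   coefficient vectors).
#' @return Numeric vector of length `2^Jc`.
#' @export
haar_iswt <- function(coeffs) {
  stopifnot(inherits(coeffs, "swt_coefficients"))
  n <- 2L^coeffs$Jc
  if (length(coeffs$approx) != n ||
      any(lengths(coeffs$details) != n))
    stop("coefficient vectors must all have length 2^Jc")
  a <- coeffs$approx
  idx <- seq_len(n) - 1L
  for (k in rev(seq_len(coeffs$depth))) {
    s <- 2L^(k - 1L)
    d <- coeffs$details[[k]]
    r1 <- (a + d) / sqrt(2)                      # reconstructs position t
    r2 <- (a - d) / sqrt(2)                      # reconstructs position t+s
    a <- 0.5 * (r1 + r2[((idx - s) %% n) + 1L])
  }
  a
}

#' Robust noise scale of one detail level
#'
#' The median absolute deviation about zero divided by the standard-normal
#' consistency constant: `sigma_j = median(|detail|) / 0.6745`.
#'
#' @param detail Numeric vector of detail coefficients at one depth.
#' @return Non-negative scalar noise-scale estimate.
#' @export
estimate_sigma <- function(detail) {
  if (length(detail) == 0L) stop("empty detail vector")
  stats::median(abs(detail)) / 0.6745
}

#' Level-dependent universal hard threshold
#'
#' `lambda_j = C * sigma_j * sqrt(2 * log(n_j))`, where `n_j` is the
#' decimated coefficient count of the level (`2^(Jc - k)` at depth `k`).
#'
#' @param sigma Noise scale at the level (>= 0).
#' @param n_level Decimated coefficient count (>= 2).
#' @param C Threshold multiplier (>= 0).
#' @return Threshold value `lambda_j`.
#' @export
level_threshold <- function(sigma, n_level, C) {
  stopifnot(sigma >= 0, C >= 0)
  if (n_level < 2) stop("n_level must be >= 2")
  C * sigma * sqrt(2 * log(n_level))
}

# keep |x| > lambda, zero the rest
hard_threshold <- function(x, lambda) {
  x[abs(x) <= lambda] <- 0
  x
}

# Per-depth thresholds for a decomposition: lambda_k = C*sigma_k*sqrt(2 ln n_k)
# with n_k = 2^(Jc-k); depths where n_k < 2 get lambda 0 (log(1) = 0 anyway).
swt_thresholds <- function(coeffs, C) {
  vapply(seq_len(coeffs$depth), function(k) {
    n_k <- 2^(coeffs$Jc - k)
    sg <- estimate_sigma(coeffs$details[[k]])
    if (n_k < 2) 0 else level_threshold(sg, n_k, C)
  }, numeric(1))
}

#' Translation-invariant low-frequency profile
#'
#' Decomposes to depth `D_low`, zeroes every detail level and synthesises:
#' a shift-invariant local average (no thresholding anywhere on this path).
#' Values are returned at the original probes only.
#'
#' @param signal A `dyadic_signal` or numeric vector.
#' @param D_low Depth (coarseness) of the average; clipped to `Jc` with a
#'   warning if larger.
#' @return Numeric vector of length `n_orig`.
#' @export
compute_low <- function(signal, D_low) {
  sig <- as_dyadic(signal)
  D_low <- as.integer(D_low)
  stopifnot(D_low >= 1L)
  if (D_low > sig$Jc) {
    warning("D_low clipped from ", D_low, " to Jc = ", sig$Jc)
    D_low <- sig$Jc
  }
  cf <- haar_swt(sig, D_low)
  for (k in seq_len(cf$depth)) cf$details[[k]][] <- 0
  haar_iswt(cf)[seq_len(sig$n_orig)]
}

#' Translation-invariant thresholded high-frequency profile
#'
#' Decomposes to depth `D_high`, hard-thresholds each detail level with its
#' level-dependent universal threshold (noise scale estimated per depth from
#' this signal's own detail coefficients), zeroes the approximation, and
#' synthesises. Equals the average over all circular shifts of
#' shift / decimated Haar transform / threshold / inverse / unshift
#' (see [cycle_spin_high_oracle()]). Values are returned at the original
#' probes only.
#'
#' @param signal A `dyadic_signal` or numeric vector.
#' @param D_high Number of fine detail depths retained, `1 <= D_high <= Jc`.
#' @param C Threshold multiplier.
#' @return Numeric vector of length `n_orig`.
#' @export
compute_high <- function(signal, D_high, C) {
  sig <- as_dyadic(signal)
  D_high <- as.integer(D_high)
  stopifnot(D_high >= 1L, D_high <= sig$Jc, C >= 0)
  cf <- haar_swt(sig, D_high)
  lam <- swt_thresholds(cf, C)
  for (k in seq_len(cf$depth))
    cf$details[[k]] <- hard_threshold(cf$details[[k]], lam[k])
  cf$approx[] <- 0
  haar_iswt(cf)[seq_len(sig$n_orig)]
}

# ---- decimated transforms (test oracles) -----------------------------------

haar_dwt <- function(x, depth) {
  details <- vector("list", depth)
  a <- x
  for (k in seq_len(depth)) {
    odd <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details[[k]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details)
}

haar_idwt <- function(dec) {
  a <- dec$approx
  for (k in rev(seq_along(dec$details))) {
    d <- dec$details[[k]]
    out <- numeric(2L * length(a))
    out[seq(1L, length(out), by = 2L)] <- (a + d) / sqrt(2)
    out[seq(2L, length(out), by = 2L)] <- (a - d) / sqrt(2)
    a <- out
  }
  a
}

#' Explicit cycle-spinning oracle for the high-frequency profile
#'
#' Brute-force reference implementation of translation-invariant denoising:
#' for every circular shift of the extended signal, take the decimated Haar
#' transform to depth `D_high`, hard-threshold every detail level with the
#' same per-level thresholds used by [compute_high()], zero the
#' approximation, invert, unshift; return the average over all shifts.
#' Intended for small test inputs.
#'
#' @inheritParams compute_high
#' @return Numeric vector of length `n_orig`.
#' @export
cycle_spin_high_oracle <- function(signal, D_high, C) {
  sig <- as_dyadic(signal)
  n <- length(sig$extended)
  D_high <- as.integer(D_high)
  stopifnot(D_high >= 1L, D_high <= sig$Jc)
  lam <- swt_thresholds(haar_swt(sig, D_high), C)
  acc <- numeric(n)
  idx <- seq_len(n) - 1L
  for (s in 0:(n - 1L)) {
    xs <- sig$extended[((idx + s) %% n) + 1L]
    dec <- haar_dwt(xs, D_high)
    for (k in seq_len(D_high))
      dec$details[[k]] <- hard_threshold(dec$details[[k]], lam[k])
    dec$approx[] <- 0
    rec <- haar_idwt(dec)
    acc <- acc + rec[((idx - s) %% n) + 1L]
  }
  (acc / n)[seq_len(sig$n_orig)]
}

#' Explicit cycle-spinning oracle for the low-frequency profile
#'
#' As [cycle_spin_high_oracle()] but keeping only the approximation (no
#' thresholding), matching [compute_low()].
#'
#' @inheritParams compute_low
#' @return Numeric vector of length `n_orig`.
#' @export
cycle_spin_low_oracle <- function(signal, D_low) {
  sig <- as_dyadic(signal)
  n <- length(sig$extended)
  D_low <- as.integer(min(D_low, sig$Jc))
  acc <- numeric(n)
  idx <- seq_len(n) - 1L
  for (s in 0:(n - 1L)) {
    xs <- sig$extended[((idx + s) %% n) + 1L]
    dec <- haar_dwt(xs, D_low)
    for (k in seq_len(D_low)) dec$details[[k]][] <- 0
    rec <- haar_idwt(dec)
    acc <- acc + rec[((idx - s) %% n) + 1L]
  }
  (acc / n)[seq_len(sig$n_orig)]
}
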