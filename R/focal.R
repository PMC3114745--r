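#' Sum post-processed high-frequency profiles across samples
#'
#' Concordant focal aberrations leave same-sign nonzero values at the same
#' probes in many samples; their sum over samples is the evidence statistic
#' that clustering and scoring operate on.
#'
#' @param profiles A `wifa_profiles` object from [wifa_transform()], or a
#'   probes x samples matrix of post-processed high-frequency values.
#' @return Numeric vector: probe-aligned sum over samples.
#' @export
sum_high <- function(profiles) {
  m <- if (inherits(profiles, "wifa_profiles")) profiles$high else profiles
  stopifnot(is.matrix(m))
  rowSums(m)
}

# split a set of (sorted) probe indices wherever the bp gap between
# consecutive members exceeds `gap` (inclusive comparison: <= gap stays)
split_by_gap <- function(idx, pos, gap) {
  if (length(idx) <= 1L) return(list(idx))
  brk <- which(diff(pos[idx]) > gap)
  unname(split(idx, cumsum(c(0L, seq_along(idx)[-1L] %in% (brk + 1L)))))
}

# Clusters on ONE chromosome. ysum: summed profile; high: probes x samples
# matrix of per-sample post-processed values; pos: bp positions.
# For each sign: nonzero same-sign positions are grouped at gaps <= group_gap,
# clustered at gaps <= d, the max-|S| cluster per group is kept (ties:
# leftmost), and clusters supported by < 2 samples are dropped.
clusters_one_chrom <- function(ysum, high, pos, params, chrom_label = "") {
  res <- list()
  for (sgn in c(1, -1)) {
    idx <- which(sign(ysum) == sgn)
    if (!length(idx)) next
    for (grp in split_by_gap(idx, pos, params$group_gap)) {
      cls <- split_by_gap(grp, pos, params$d)
      scores <- vapply(cls, function(m) sum(ysum[m]), numeric(1))
      best <- cls[[which.max(abs(scores))]]
      npat <- sum(apply(high[best, , drop = FALSE], 2L,
                        function(col) any(sign(col) == sgn)))
      if (npat < 2L) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom_label,
        start = pos[best[1L]], end = pos[best[length(best)]],
        first_probe = best[1L], last_probe = best[length(best)],
        sign = sgn, score = sum(ysum[best]), n_patients = npat,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_cluster_frame())
  do.call(rbind, res)
}

empty_cluster_frame <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             first_probe = integer(), last_probe = integer(),
             sign = numeric(), score = numeric(), n_patients = integer(),
             stringsAsFactors = FALSE)
}

#' Build candidate focal clusters from summed profiles
#'
#' Per chromosome and per sign: positions with nonzero same-sign summed
#' values are grouped wherever consecutive positions lie within
#' `params$group_gap` (1 Mb by default); within each group, clusters are
#' maximal subsets with consecutive gaps within `params$d`; only the cluster
#' with the largest absolute score `S(c) = sum of the summed profile over its
#' probes` survives per group (ties: leftmost); clusters whose nonzero
#' contributions come from fewer than two samples are removed. Gap
#' comparisons are inclusive.
#'
#' @param profiles A `wifa_profiles` object.
#' @param summed Optional precomputed [sum_high()] vector.
#' @return Data frame of clusters: `chrom`, `start`/`end` (1-based bp over
#'   member probes), probe index range, `sign`, `score`, `n_patients`.
#' @export
build_clusters <- function(profiles, summed = sum_high(profiles)) {
  stopifnot(inherits(profiles, "wifa_profiles"))
  out <- lapply(names(chrom_indices(profiles)), function(cc) {
    ix <- which(profiles$chrom == cc)
    cl <- clusters_one_chrom(summed[ix],
                             profiles$high[ix, , drop = FALSE],
                             profiles$pos[ix], profiles$params, cc)
    cl$first_probe <- cl$first_probe + ix[1L] - 1L
    cl$last_probe <- cl$last_probe + ix[1L] - 1L
    cl
  })
  do.call(rbind, c(list(empty_cluster_frame()), out))
}

#' Randomly reposition aberration segments along a chromosome
#'
#' Implements the segment-permutation null: maximal runs of nonzero values
#' ("segments") keep their internal value vectors but are placed in a random
#' order, with the zero-valued probes distributed among the
#' `n_segments + 1` gaps by a uniformly random weak composition (every
#' non-overlapping arrangement is equally likely). Uses R's global RNG.
#'
#' @param v One sample's post-processed high-frequency values on one
#'   chromosome.
#' @return Permuted vector with the identical multiset of segments.
#' @export
permute_segments <- function(v) {
  segs <- segment_list(v)
  if (!length(segs)) return(v)
  place_segments(segs, length(v))
}

segment_list <- function(v) {
  r <- rle(v != 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) v[starts[i]:ends[i]])
}

place_segments <- function(segs, n) {
  ns <- length(segs)
  z <- n - sum(lengths(segs))
  ord <- if (ns > 1L) sample.int(ns) else 1L
  # one zero is reserved for each internal gap so that distinct segments
  # never merge (maximal runs always had >= 1 zero between them, so
  # z >= ns - 1); the remaining zeros fall uniformly over the ns + 1 gaps.
  zfree <- z - (ns - 1L)
  if (zfree < 0L) stop("segments do not fit with separating gaps")
  gaps <- if (zfree == 0L) integer(ns + 1L) else
    diff(c(0L, sort(sample.int(zfree + ns, ns)), zfree + ns + 1L)) - 1L
  if (ns > 1L) gaps[2:ns] <- gaps[2:ns] + 1L
  out <- numeric(n)
  at <- gaps[1L]
  for (i in seq_len(ns)) {
    seg <- segs[[ord[i]]]
    out[(at + 1L):(at + length(seg))] <- seg
    at <- at + length(seg) + gaps[i + 1L]
  }
  out
}

#' Permutation p-values for focal clusters
#'
#' For each chromosome, every sample's profile is segment-permuted
#' ([permute_segments()]) `params$N` times; after each permutation the
#' profiles are re-summed and re-clustered by the full observed procedure
#' (group/cluster construction, per-group maximum, single-patient filter),
#' and the maximum absolute cluster score per sign is recorded (0 when no
#' cluster forms). The p-value of an observed cluster `c` is the fraction of
#' permutations whose maximum score reaches `|S(c)|`:
#' `P = (1/N) * sum_i I(max_score(i) >= |S(c)|)`, with separate nulls for
#' amplification and deletion clusters.
#'
#' @param clusters Data frame from [build_clusters()].
#' @param profiles The `wifa_profiles` the clusters came from.
#' @return `clusters` with columns `p_cluster`, `significant`
#'   (`p_cluster < params$alpha`) and `rank` (by `|score|`, significant
#'   clusters only, `NA` otherwise) added.
#' @export
cluster_pvalues <- function(clusters, profiles) {
  stopifnot(inherits(profiles, "wifa_profiles"))
  params <- profiles$params
  if (params$N < 1L) stop("params$N must be >= 1")
  clusters[["p_cluster"]] <- rep(NA_real_, nrow(clusters))
  if (nrow(clusters)) {
    for (cc in unique(clusters$chrom)) {
      ix <- which(profiles$chrom == cc)
      mx <- perm_max_scores(profiles$high[ix, , drop = FALSE],
                            profiles$pos[ix], params)
      for (i in which(clusters$chrom == cc)) {
        null_max <- mx[, if (clusters$sign[i] > 0) "amp" else "del"]
        clusters$p_cluster[i] <- permutation_pvalue(clusters$score[i],
                                                    null_max)
      }
    }
  }
  clusters$significant <- clusters$p_cluster < params$alpha
  clusters <- clusters[order(-abs(clusters$score)), , drop = FALSE]
  clusters[["rank"]] <- rep(NA_integer_, nrow(clusters))
  if (any(clusters$significant))
    clusters$rank[clusters$significant] <- seq_len(sum(clusters$significant))
  rownames(clusters) <- NULL
  clusters
}

#' Permutation p-value of one cluster score
#'
#' `P = (1/N) * sum_i I(max_score(i) >= |S|)`: the fraction of permutation
#' maxima reaching the observed absolute cluster score.
#'
#' @param score Observed (signed) cluster score `S(c)`.
#' @param max_scores Numeric vector of per-permutation maximum absolute
#'   scores (length `N`).
#' @return p-value on the grid `0, 1/N, ..., 1`.
#' @examples
#' permutation_pvalue(2, c(5, 1, 2, 3))  # 3/4
#' @export
permutation_pvalue <- function(score, max_scores) {
  if (!length(max_scores)) stop("need at least one permutation")
  mean(max_scores >= abs(score))
}

# N x 2 matrix of per-permutation max |S| for amp and del clusters on one
# chromosome
perm_max_scores <- function(high, pos, params) {
  n <- nrow(high)
  ns <- ncol(high)
  segs <- lapply(seq_len(ns), function(j) segment_list(high[, j]))
  mx <- matrix(0, params$N, 2L, dimnames = list(NULL, c("amp", "del")))
  perm <- matrix(0, n, ns)
  for (i in seq_len(params$N)) {
    for (j in seq_len(ns)) {
      perm[, j] <- if (length(segs[[j]]))
        place_segments(segs[[j]], n) else 0
    }
    cl <- clusters_one_chrom(rowSums(perm), perm, pos, params)
    if (nrow(cl)) {
      a <- abs(cl$score[cl$sign > 0])
      d <- abs(cl$score[cl$sign < 0])
      if (length(a)) mx[i, "amp"] <- max(a)
      if (length(d)) mx[i, "del"] <- max(d)
    }
  }
  mx
}

#' Detect focal copy-number aberrations
#'
#' The full multi-sample focal pipeline: per-sample wavelet profiles
#' ([wifa_transform()]), cross-sample summation ([sum_high()]), clustering
#' ([build_clusters()]) and permutation significance ([cluster_pvalues()]).
#' Deterministic for a fixed `params$seed`.
#'
#' @param pm A [probe_matrix()] of log2 ratios.
#' @param params A [wifa_params()]; `J_total` defaults to
#'   `ceiling(log2(n_probes))`.
#' @param profiles Optional precomputed `wifa_profiles` (skips the wavelet
#'   step).
#' @return A `wifa_focal` object: list with `clusters` (all candidates, with
#'   p-values and significance flags, ordered by `|score|`), `summed` (the
#'   probe-aligned summed profile), `profiles`, and `params`.
#' @export
detect_focal <- function(pm, params = wifa_params(), profiles = NULL) {
  if (is.null(profiles)) {
    stopifnot(inherits(pm, "probe_matrix"))
    params <- resolve_params(params, length(pm$pos))
    profiles <- wifa_transform(pm, params)
  }
  params <- profiles$params
  if (!is.null(params$seed)) set.seed(params$seed)
  summed <- sum_high(profiles)
  clusters <- build_clusters(profiles, summed)
  clusters <- cluster_pvalues(clusters, profiles)
  structure(list(clusters = clusters, summed = summed,
                 profiles = profiles, params = params),
            class = "wifa_focal")
}

#' @export
print.wifa_focal <- function(x, ...) {
  ns <- sum(x$clusters$significant)
  cat(sprintf("wifa_focal: %d candidate cluster(s), %d significant at alpha = %g\n",
              nrow(x$clusters), ns, x$params$alpha))
  if (ns) print(utils::head(
    x$clusters[x$clusters$significant,
               c("chrom", "start", "end", "score", "n_patients",
                 "p_cluster", "rank")], 10L))
  invisible(x)
}
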