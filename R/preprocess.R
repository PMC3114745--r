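#' Convert raw tumor/normal intensities to log2 ratios
#'
#' Reproduces the standard SNP-array preprocessing chain: (i) log2-transform
#' intensities to stabilise the noise, (ii) median-centre every sample
#' (subtract its median across all probes), (iii) subtract the centred normal
#' from the centred tumor to obtain log2 ratios, and (iv) drop probes at
#' known germline CNV positions. Median-centring makes the result invariant
#' to rescaling any sample's intensities by a positive constant.
#'
#' @param tumor,normal [probe_matrix()] objects holding strictly positive raw
#'   intensities on an identical probe grid. With `reference = "paired"` the
#'   two must have the same number of columns (normal i matched to tumor i);
#'   with `reference = "median"` the median centred-normal profile is
#'   subtracted from every tumor sample (for unpaired designs).
#' @param exclusion Optional [region_annotation()] of CNV positions to drop.
#' @param reference `"paired"` (default) or `"median"`.
#' @return A [probe_matrix()] of log2 ratios carrying the tumor sample ids.
#' @export
preprocess_intensities <- function(tumor, normal, exclusion = NULL,
                                   reference = c("paired", "median")) {
  reference <- match.arg(reference)
  stopifnot(inherits(tumor, "probe_matrix"), inherits(normal, "probe_matrix"))
  if (!identical(tumor$chrom, normal$chrom) ||
      !identical(tumor$pos, normal$pos))
    stop("tumor and normal probe grids differ")
  if (any(tumor$values <= 0) || any(normal$values <= 0))
    stop("intensities must be strictly positive (log2 undefined)")
  centre <- function(m) {
    lg <- log2(m)
    sweep(lg, 2L, apply(lg, 2L, stats::median))
  }
  t_c <- centre(tumor$values)
  n_c <- centre(normal$values)
  if (reference == "paired") {
    if (ncol(t_c) != ncol(n_c))
      stop("paired preprocessing needs one normal column per tumor column")
    ratio <- t_c - n_c
  } else {
    ratio <- t_c - apply(n_c, 1L, stats::median)
  }
  pm <- probe_matrix(tumor$chrom, tumor$pos, ratio, tumor$sample_ids)
  if (!is.null(exclusion) && nrow(exclusion) > 0L)
    pm <- filter_probes_by_regions(pm, exclusion)
  pm
}
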