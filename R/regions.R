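#' Read a BED-like region annotation
#'
#' Parses chromosome-arm definitions or germline-CNV exclusion lists from a
#' tab-separated file with columns `chrom, start, end[, label]` in 0-based
#' half-open coordinates.
#'
#' @param path Path to a BED-like TSV (no header).
#' @param kind `"arms"` (records must not overlap within a chromosome) or
#'   `"exclusion"`.
#' @param known_chroms Optional character vector; region chromosomes absent
#'   from it trigger a warning (records are kept).
#' @return A `region_annotation`: data.frame with columns `chrom`, `start`,
#'   `end`, `label`.
#' @export
read_regions <- function(path, kind = c("arms", "exclusion"),
                         known_chroms = NULL) {
  kind <- match.arg(kind)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty region file: ", path)
    return(region_annotation(character(), integer(), integer(), character(),
                             kind = kind))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  label <- if (ncol(dt) >= 4L) as.character(dt[[4]]) else
    paste0("region", seq_len(nrow(dt)))
  reg <- region_annotation(as.character(dt[[1]]), dt[[2]], dt[[3]], label,
                           kind = kind)
  if (!is.null(known_chroms)) {
    unk <- setdiff(unique(reg$chrom), known_chroms)
    if (length(unk))
      warning("region chromosome(s) not in data: ",
              paste(unk, collapse = ", "))
  }
  reg
}

#' Construct a region annotation
#'
#' @param chrom,start,end,label Parallel vectors; `start`/`end` are 0-based
#'   half-open base-pair coordinates with `start < end`.
#' @param kind `"arms"` or `"exclusion"`; arm records must partition, so
#'   overlaps within a chromosome are rejected.
#' @return A data.frame of class `region_annotation`.
#' @export
region_annotation <- function(chrom, start, end, label = NULL,
                              kind = c("arms", "exclusion")) {
  kind <- match.arg(kind)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom)) {
    if (any(start < 0)) stop("region start coordinates must be non-negative")
    if (any(start >= end)) stop("region start must be < end")
  }
  if (is.null(label)) label <- paste0("region", seq_along(chrom))
  reg <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), stringsAsFactors = FALSE)
  reg <- reg[order(match(reg$chrom, unique(reg$chrom)), reg$start), ]
  if (kind == "arms" && nrow(reg) > 1L) {
    for (cc in unique(reg$chrom)) {
      r <- reg[reg$chrom == cc, ]
      if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
        stop("arm records overlap on ", cc, "; arms must partition")
    }
  }
  rownames(reg) <- NULL
  class(reg) <- c("region_annotation", "data.frame")
  attr(reg, "kind") <- kind
  reg
}

# TRUE for each (chrom, pos) [1-based] lying inside any region
# [start, end) [0-based half-open], i.e. start < pos <= end.
positions_in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  if (is.null(regions) || nrow(regions) == 0L) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  hit
}

#' Remove probes lying inside annotated regions
#'
#' Used to drop probes at known germline copy-number-variant positions before
#' somatic aberration calling.
#'
#' @param pm A [probe_matrix()].
#' @param regions A [region_annotation()] (exclusion list).
#' @return The filtered `probe_matrix`.
#' @export
filter_probes_by_regions <- function(pm, regions) {
  drop <- positions_in_regions(pm$chrom, pm$pos, regions)
  if (all(drop)) stop("exclusion regions cover every probe")
  if (!any(drop)) return(pm)
  probe_matrix(pm$chrom[!drop], pm$pos[!drop],
               pm$values[!drop, , drop = FALSE], pm$sample_ids)
}
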