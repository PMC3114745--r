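#' Probe-level log2-ratio matrix
#'
#' The central container: probes ordered along each chromosome, one numeric
#' column per tumor sample. Values are log2(tumor/normal) ratios
#' (dimensionless; 0 = copy-neutral) unless the object holds raw intensities
#' on their way through [preprocess_intensities()].
#'
#' @param chrom Character vector of chromosome labels, one per probe.
#' @param pos Integer vector of 1-based base-pair positions.
#' @param values Numeric matrix, probes x samples.
#' @param sample_ids Column names for `values`.
#' @return An object of class `probe_matrix`: a list with elements `chrom`,
#'   `pos`, `values` (matrix with column names) and `sample_ids`.
#' @examples
#' pm <- probe_matrix(rep("chr1", 3), c(100L, 200L, 300L),
#'                    matrix(0, 3, 2), c("s1", "s2"))
#' @export
probe_matrix <- function(chrom, pos, values, sample_ids = colnames(values)) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  n <- length(chrom)
  if (n == 0L) stop("probe_matrix: no probes")
  stopifnot(length(pos) == n, nrow(values) == n)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(ncol(values)))
  stopifnot(length(sample_ids) == ncol(values))
  colnames(values) <- sample_ids
  if (anyNA(pos) || any(pos < 1L)) stop("positions must be positive integers")
  if (!all(is.finite(values))) stop("all log2-ratio values must be finite")

  # sort by (chromosome in order of first appearance, position)
  clev <- unique(chrom)
  o <- order(match(chrom, clev), pos)
  if (is.unsorted(o)) {
    warning("probes were not sorted by (chromosome, position); sorting")
    chrom <- chrom[o]; pos <- pos[o]
    values <- values[o, , drop = FALSE]
  }
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chromosome, position) pairs are not allowed")
  by_chr <- split(pos, factor(chrom, levels = clev))
  stopifnot(all(vapply(by_chr, function(p) !is.unsorted(p, strictly = TRUE),
                       logical(1))))
  structure(list(chrom = chrom, pos = pos, values = values,
                 sample_ids = sample_ids),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples on %d chromosome(s)\n",
              length(x$pos), ncol(x$values), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$values)

chrom_indices <- function(pm) {
  split(seq_along(pm$chrom), factor(pm$chrom, levels = unique(pm$chrom)))
}

#' Read a probe-level log2-ratio matrix from TSV
#'
#' Expects a header line `Chrom<TAB>Position<TAB><sample1>...` followed by
#' one row per probe. Rows may arrive unsorted (they are sorted with a
#' warning); duplicate (chromosome, position) pairs and non-numeric or
#' missing cells are errors.
#'
#' @param path Path to a tab-separated file.
#' @return A [probe_matrix()].
#' @export
read_probe_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L) stop("empty probe matrix file: ", path)
  nms <- names(dt)
  if (length(nms) < 3L || tolower(nms[1]) != "chrom" ||
      tolower(nms[2]) != "position")
    stop("expected header columns 'Chrom', 'Position', then sample columns")
  vals <- as.matrix(dt[, -(1:2)])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(apply(vals, 1L, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric or missing log2 ratio at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(dt[[2]]))
  if (anyNA(pos)) stop("non-integer probe position in ", path)
  probe_matrix(dt[[1]], pos, vals, sample_ids = nms[-(1:2)])
}

#' Drop sex chromosomes
#'
#' Autosome-only analysis is the default convention for copy-number calling
#' from tumor/normal pairs of mixed sex.
#'
#' @param pm A [probe_matrix()].
#' @param labels Chromosome labels to drop.
#' @return A filtered `probe_matrix`.
#' @export
drop_sex_chromosomes <- function(pm, labels = c("chrX", "chrY", "X", "Y")) {
  keep <- !(pm$chrom %in% labels)
  if (!any(keep)) stop("no probes left after dropping sex chromosomes")
  probe_matrix(pm$chrom[keep], pm$pos[keep], pm$values[keep, , drop = FALSE],
               pm$sample_ids)
}
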