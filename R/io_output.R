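#' Write analysis outputs to disk
#'
#' Writes focal clusters as BED (0-based half-open: the 1-based inclusive
#' probe span `start..end` becomes `start-1, end`), any number of per-probe
#' tracks as bedGraph, and a `run_params.txt` file recording every parameter.
#'
#' @param clusters Data frame from [detect_focal()]'s `clusters` element (may
#'   be empty).
#' @param tracks Named list of probe-aligned numeric vectors (e.g. the summed
#'   high-frequency profile, summed low-frequency profile, q-values).
#' @param chrom,pos Probe grid the tracks align to (needed when `tracks` is
#'   non-empty).
#' @param out_dir Output directory (created if missing).
#' @param params Optional [wifa_params()] to record.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(clusters, tracks = list(), chrom = NULL,
                          pos = NULL, out_dir, params = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character()

  bed_path <- file.path(out_dir, "clusters.bed")
  header <- paste("#chrom", "start", "end", "name", "score", "sign",
                  "n_patients", "p_cluster", sep = "\t")
  if (!is.null(clusters) && nrow(clusters)) {
    name <- if ("rank" %in% names(clusters) && !all(is.na(clusters$rank)))
      ifelse(is.na(clusters$rank), ".", paste0("cluster_", clusters$rank))
    else paste0("cluster_", seq_len(nrow(clusters)))
    bed <- data.frame(chrom = clusters$chrom,
                      start = format_bp(clusters$start - 1),
                      end = format_bp(clusters$end),
                      name = name,
                      score = clusters$score,
                      sign = ifelse(clusters$sign > 0, "+", "-"),
                      n_patients = clusters$n_patients,
                      p_cluster = if ("p_cluster" %in% names(clusters))
                        clusters$p_cluster else NA_real_)
    writeLines(header, bed_path)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  } else {
    writeLines(header, bed_path)
  }
  paths <- c(paths, bed_path)

  for (nm in names(tracks)) {
    stopifnot(!is.null(chrom), !is.null(pos),
              length(tracks[[nm]]) == length(pos))
    tp <- file.path(out_dir, paste0(nm, ".bedGraph"))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", nm), tp)
    utils::write.table(
      data.frame(chrom, format_bp(pos - 1), format_bp(pos), tracks[[nm]]),
      tp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
      append = TRUE)
    paths <- c(paths, tp)
  }

  if (!is.null(params)) {
    pp <- file.path(out_dir, "run_params.txt")
    flat <- params[!vapply(params, is.null, logical(1))]
    writeLines(sprintf("%s=%s", names(flat),
                       vapply(flat, function(v) paste(format(v), collapse = ","),
                              character(1))), pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write a probe matrix to TSV
#'
#' Inverse of [read_probe_matrix()]: header `Chrom, Position, <samples>`.
#'
#' @param pm A [probe_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probe_matrix <- function(pm, path) {
  dt <- data.table::data.table(Chrom = pm$chrom, Position = pm$pos)
  for (j in seq_along(pm$sample_ids))
    data.table::set(dt, j = pm$sample_ids[j], value = pm$values[, j])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
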