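#' Write a probe table to TSV
#'
#' One row per probe: `probe_id`, `chrom`, `pos` (1-based), `grid_x`,
#' `grid_y`, `test_intensity`, `ref_intensity`, plus any extra columns
#' present (e.g. `log2ratio`).  Header line always written.
#'
#' @param probes a `probe_table`.
#' @param path output file.
#' @export
write_probe_table <- function(probes, path) {
  write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a probe table TSV
#'
#' @param path a [write_probe_table()] file.
#' @return a `probe_table` data.frame (and `probe_layout` if only layout
#'   columns are present).
#' @export
read_probe_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  need <- c("probe_id", "chrom", "pos", "grid_x", "grid_y")
  if (!all(need %in% names(tab))) {
    stop("probe table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  cls <- c("probe_layout", "data.frame")
  if ("test_intensity" %in% names(tab)) cls <- c("probe_table", cls)
  class(tab) <- cls
  tab
}

#' Write truth regions as BED
#'
#' On disk BED is 0-based half-open; internal coordinates are 1-based
#' inclusive, so `start - 1` is written.  Column 4 holds the CNV class,
#' column 5 the log2 shift.
#'
#' @param truth a [implant_truth()] truth set or its `regions` data.frame.
#' @param path output file.
#' @export
write_truth_bed <- function(truth, path) {
  regions <- if (inherits(truth, "truth_set")) truth$regions else truth
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = regions$cnv_class,
                    score = regions$log2_shift)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read truth regions from BED
#'
#' @param path a [write_truth_bed()] file.
#' @return truth-region `data.frame` (1-based inclusive coordinates).
#' @export
read_truth_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty_truth_regions())
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(V1 = "character"))
  data.frame(chrom = bed$V1, start = bed$V2 + 1L, end = bed$V3,
             cnv_class = bed$V4, log2_shift = bed$V5,
             stringsAsFactors = FALSE)
}

#' Write segments or calls as BED-like TSV
#'
#' Coordinates go to disk 0-based half-open (`start_bp - 1`, `end_bp`);
#' all other columns are kept as-is.
#'
#' @param segments a segment or call table with `start_bp`/`end_bp`.
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  out <- as.data.frame(segments)
  out$start_bp <- out$start_bp - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a [write_segments()] TSV back (restoring 1-based starts)
#'
#' @param path input file.
#' @return the segment/call table.
#' @export
read_segments <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  tab$start_bp <- tab$start_bp + 1L
  if ("cnv_class" %in% names(tab)) class(tab) <- c("cnv_calls", "data.frame")
  tab
}
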