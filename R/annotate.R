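#' Normalize chromosome names across dialects
#'
#' Maps `"chr12"` and `"12"` to the common form `"12"` so features and calls
#' from differently styled files can be overlapped.
#'
#' @param x character vector of chromosome names.
#' @return normalized names.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read genomic features from BED or GFF
#'
#' Parses via rtracklayer and converts to the internal 1-based inclusive
#' convention (BED on disk is 0-based half-open; GFF is already 1-based
#' inclusive).  Chromosome names are normalized with [normalize_chrom()].
#'
#' @param path file path.
#' @param format `"bed"` or `"gff"`; default guessed from the extension.
#' @param feature_type label attached to all records (e.g. `"gene"`,
#'   `"miRNA"`).
#' @return a `GRanges` with metadata columns `name` and `feature_type`.
#' @export
read_features <- function(path, format = NULL, feature_type = "gene") {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff" else "bed"
  }
  format <- match.arg(tolower(format), c("bed", "gff"))
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e)))
  if (length(gr)) {
    nm <- if (!is.null(gr$name)) as.character(gr$name)
          else if (!is.null(gr$Name)) as.character(gr$Name)
          else if (!is.null(gr$ID)) as.character(gr$ID)
          else sprintf("feature_%d", seq_along(gr))
  } else nm <- character()
  out <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(GenomicRanges::seqnames(gr)),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr))
  out$name <- nm
  out$feature_type <- rep(feature_type, length(out))
  dup <- duplicated(nm)
  if (any(dup)) warning("duplicated feature names: ",
                        paste(unique(nm[dup]), collapse = ", "))
  out
}

regions_to_granges <- function(regions) {
  if (methods::is(regions, "GRanges")) return(regions)
  start <- regions$start_bp %||% regions$start
  end <- regions$end_bp %||% regions$end
  GenomicRanges::GRanges(
    seqnames = normalize_chrom(regions$chrom),
    ranges = IRanges::IRanges(start = start, end = end))
}

#' Map features onto regions by interval overlap
#'
#' A feature maps to a region iff their closed intervals share at least one
#' base pair; strand is ignored.  Feature names are listed in genomic order.
#'
#' @param regions a `data.frame` with `chrom` and `start_bp`/`end_bp` (or
#'   `start`/`end`) columns — e.g. recurrence or call tables.
#' @param features a [read_features()] `GRanges` (or a data.frame with the
#'   same columns as `regions` plus `name`).
#' @return `regions` with a `features` column (comma-separated names).
#' @export
overlap_features <- function(regions, features) {
  if (!methods::is(features, "GRanges")) {
    fg <- regions_to_granges(features)
    fg$name <- features$name
    features <- fg
  }
  rg <- regions_to_granges(regions)
  shared <- intersect(as.character(unique(GenomicRanges::seqnames(rg))),
                      as.character(unique(GenomicRanges::seqnames(features))))
  if (length(rg) && length(features) && length(shared) == 0L) {
    warning("no chromosome shared between regions and features; ",
            "check chromosome naming")
  }
  features <- features[order(as.character(GenomicRanges::seqnames(features)),
                             GenomicRanges::start(features))]
  h <- GenomicRanges::findOverlaps(rg, features, ignore.strand = TRUE)
  lst <- split(features$name[S4Vectors::subjectHits(h)],
               factor(S4Vectors::queryHits(h), levels = seq_along(rg)))
  regions$features <- vapply(lst, function(v) paste(unique(v), collapse = ","), "")
  regions
}

CIRCOS_COLORS <- c(gain = "orange", loss = "purple",
                   amplification = "red", deletion = "green")

#' Write Circos data tracks for CNV calls
#'
#' One plain-text data file per class (gain, loss, amplification, deletion),
#' with records `chrom start end color=<class color>` in deterministic
#' genomic order.  The class-to-color legend is gain = orange, loss =
#' purple, amplification = red, deletion = green.
#'
#' @param calls a `cnv_calls` table.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
write_circos_tracks <- function(calls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in names(CIRCOS_COLORS)) {
    path <- file.path(out_dir, paste0(cl, ".txt"))
    sub <- calls[calls$cnv_class == cl, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$start_bp), , drop = FALSE]
    con <- file(path, "w")
    writeLines(sprintf("# class=%s color=%s", cl, CIRCOS_COLORS[[cl]]), con)
    if (nrow(sub)) {
      writeLines(sprintf("%s %d %d color=%s", sub$chrom, sub$start_bp,
                         sub$end_bp, CIRCOS_COLORS[[cl]]), con)
    }
    close(con)
    paths[cl] <- path
  }
  invisible(paths)
}

#' Read one Circos data track back into a table
#'
#' @param path a file written by [write_circos_tracks()].
#' @return `data.frame` with `chrom`, `start_bp`, `end_bp`, `cnv_class`.
#' @export
read_circos_track <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")][1]
  cl <- sub(".*class=(\\S+).*", "\\1", header)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), cnv_class = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, " ")
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start_bp = as.integer(vapply(parts, `[`, "", 2)),
             end_bp = as.integer(vapply(parts, `[`, "", 3)),
             cnv_class = cl, stringsAsFactors = FALSE)
}
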