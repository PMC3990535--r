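#' Minimal common regions of a cohort's CNV calls
#'
#' The union of all call breakpoints on a chromosome partitions the covered
#' footprint into atomic intervals over which per-sample carriage is
#' constant.  Each atom's per-class count is the number of distinct samples
#' whose call of that class covers it, with class nesting applied: an
#' amplification call also counts toward gain, a deletion call toward loss.
#' Adjacent atoms with identical count vectors are merged.
#'
#' @param calls combined `cnv_calls` of the cohort (or a list of per-sample
#'   call tables, which is row-bound); columns `chrom`, `start_bp`, `end_bp`,
#'   `sample_id`, `cnv_class`.
#' @param n_samples cohort size; defaults to the number of distinct
#'   `sample_id`s in `calls` (supply explicitly if some samples have no
#'   calls).
#' @return `data.frame` of class `freq_regions`, sorted by chromosome then
#'   start: `chrom`, `start_bp`, `end_bp` (1-based inclusive),
#'   `n_samples_total`, `count_gain`, `count_loss`, `count_amplification`,
#'   `count_deletion` and matching `freq_*` columns (counts /
#'   `n_samples_total`).
#' @export
minimal_common_regions <- function(calls, n_samples = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  need <- c("chrom", "start_bp", "end_bp", "sample_id", "cnv_class")
  stopifnot(all(need %in% names(calls)))
  if (any(calls$start_bp > calls$end_bp)) stop("call with start_bp > end_bp")
  if (is.null(n_samples)) n_samples <- length(unique(calls$sample_id))
  stopifnot(n_samples >= 1)

  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_samples_total = integer(),
                      count_gain = integer(), count_loss = integer(),
                      count_amplification = integer(), count_deletion = integer(),
                      freq_gain = numeric(), freq_loss = numeric(),
                      freq_amplification = numeric(), freq_deletion = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) {
    class(empty) <- c("freq_regions", "data.frame")
    return(empty)
  }

  gr <- GenomicRanges::GRanges(
    seqnames = as.character(calls$chrom),
    ranges = IRanges::IRanges(start = calls$start_bp, end = calls$end_bp),
    sample_id = as.character(calls$sample_id),
    cnv_class = as.character(calls$cnv_class))
  atoms <- GenomicRanges::disjoin(gr)

  # class nesting: amplification c gain, deletion c loss
  effective <- list(
    gain = c("gain", "amplification"),
    loss = c("loss", "deletion"),
    amplification = "amplification",
    deletion = "deletion")
  counts <- sapply(effective, function(cl) {
    sub <- gr[gr$cnv_class %in% cl]
    if (length(sub) == 0L) return(integer(length(atoms)))
    h <- GenomicRanges::findOverlaps(atoms, sub)
    # distinct samples per atom (a sample contributes at most 1)
    pairs <- unique(data.frame(a = S4Vectors::queryHits(h),
                               s = sub$sample_id[S4Vectors::subjectHits(h)]))
    tab <- table(factor(pairs$a, levels = seq_along(atoms)))
    as.integer(tab)
  })
  if (length(atoms) == 1L) counts <- matrix(counts, nrow = 1,
                                            dimnames = list(NULL, names(effective)))

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(atoms)),
    start_bp = GenomicRanges::start(atoms),
    end_bp = GenomicRanges::end(atoms),
    count_gain = counts[, "gain"],
    count_loss = counts[, "loss"],
    count_amplification = counts[, "amplification"],
    count_deletion = counts[, "deletion"],
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]

  # merge adjacent atoms with identical count vectors
  key <- paste(df$count_gain, df$count_loss, df$count_amplification,
               df$count_deletion)
  new_run <- c(TRUE, !(df$chrom[-1] == df$chrom[-nrow(df)] &
                       df$start_bp[-1] == df$end_bp[-nrow(df)] + 1L &
                       key[-1] == key[-nrow(df)]))
  run <- cumsum(new_run)
  merged <- do.call(rbind, lapply(split(df, run), function(d) {
    d$end_bp[1] <- d$end_bp[nrow(d)]
    d[1, , drop = FALSE]
  }))
  rownames(merged) <- NULL
  merged$n_samples_total <- as.integer(n_samples)
  for (cl in names(effective)) {
    merged[[paste0("freq_", cl)]] <- merged[[paste0("count_", cl)]] / n_samples
  }
  merged <- merged[, names(empty)]
  class(merged) <- c("freq_regions", "data.frame")
  merged
}

#' Recurrent regions at a cohort frequency threshold
#'
#' Selects regions whose maximum frequency over the requested classes is at
#' least `threshold`.  The comparison is inclusive: a region altered in
#' exactly 50% of samples is recurrent at the default threshold.
#'
#' @param regions a [minimal_common_regions()] table.
#' @param classes classes considered (default gain and loss).
#' @param threshold cohort-frequency cutoff in (0, 1]; default 0.5.
#' @return the recurrent subset of `regions`.
#' @export
recurrent_regions <- function(regions, classes = c("gain", "loss"),
                              threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1,
            all(classes %in% c("gain", "loss", "amplification", "deletion")))
  freq_cols <- paste0("freq_", classes)
  top <- do.call(pmax, regions[freq_cols])
  out <- regions[top >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency table for one focal class (amplification or deletion)
#'
#' Lists regions where the given class reaches at least `threshold` of the
#' cohort (inclusive), sorted by chromosome then position, optionally with
#' overlapping feature names attached.
#'
#' @param regions a [minimal_common_regions()] table.
#' @param cnv_class `"amplification"` or `"deletion"`.
#' @param threshold frequency cutoff in (0, 1]; default 0.2.
#' @param features optional feature set ([read_features()]) used to fill a
#'   `features` column by interval overlap.
#' @return `data.frame`: `chrom`, `start_bp`, `end_bp`, `frequency_pct`,
#'   and `features` (comma-separated, `""` when no feature file given).
#' @export
class_frequency_table <- function(regions, cnv_class = c("amplification", "deletion"),
                                  threshold = 0.2, features = NULL) {
  cnv_class <- match.arg(cnv_class)
  stopifnot(threshold > 0, threshold <= 1)
  sel <- regions[regions[[paste0("freq_", cnv_class)]] >= threshold, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start_bp), , drop = FALSE]
  out <- data.frame(
    chrom = sel$chrom, start_bp = sel$start_bp, end_bp = sel$end_bp,
    frequency_pct = 100 * sel[[paste0("freq_", cnv_class)]],
    stringsAsFactors = FALSE)
  out$features <- if (!is.null(features) && nrow(out)) {
    overlap_features(out, features)$features
  } else rep("", nrow(out))
  rownames(out) <- NULL
  out
}
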