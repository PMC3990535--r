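#' Five-way copy-number classification of a segment mean
#'
#' Thresholds (all inclusive): mean log2 ratio >= 1.0 is amplification,
#' >= 0.25 gain, <= -0.25 loss, <= -1.0 deletion; in between is unchanged.
#'
#' @param mean_log2 numeric vector of segment mean log2 ratios (finite).
#' @param gain_threshold,amp_threshold positive class bounds (defaults 0.25
#'   and 1.0); losses/deletions use the negated values.
#' @return character vector of classes in
#'   `c("deletion", "loss", "unchanged", "gain", "amplification")`.
#' @export
classify_segment <- function(mean_log2, gain_threshold = 0.25,
                             amp_threshold = 1.0) {
  if (!all(is.finite(mean_log2))) stop("non-finite segment mean")
  stopifnot(gain_threshold > 0, amp_threshold > gain_threshold)
  ifelse(mean_log2 >= amp_threshold, "amplification",
    ifelse(mean_log2 >= gain_threshold, "gain",
      ifelse(mean_log2 <= -amp_threshold, "deletion",
        ifelse(mean_log2 <= -gain_threshold, "loss", "unchanged"))))
}

#' Retention filter for segments
#'
#' Keeps exactly the segments with at least `min_probes` consecutive probes
#' and `|mean_log2| >= min_abs_mean` (both bounds inclusive); order is
#' preserved.
#'
#' @param segments a [segment_sample()] table.
#' @param min_probes minimum probe count (default 5).
#' @param min_abs_mean minimum absolute mean log2 ratio (default 0.25).
#' @return the retained subset of `segments`.
#' @export
retain_segments <- function(segments, min_probes = 5L, min_abs_mean = 0.25) {
  keep <- segments$n_probes >= min_probes & abs(segments$mean_log2) >= min_abs_mean
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call CNVs for one sample
#'
#' Applies the retention filter then the five-way classification; segments
#' classified "unchanged" are never emitted (the retention bound equals the
#' gain/loss bound, so retained segments are always called).  Calls of the
#' same class separated by at most `max_gap_probes` probes are then merged
#' into one call — a single copy-number event that the change-point search
#' split (e.g. around an isolated noisy probe) is reported once, with the
#' merged mean weighted by probe counts.
#'
#' @param segments segment table for one sample.
#' @param sample_id sample label attached to every call.
#' @param min_probes,min_abs_mean see [retain_segments()].
#' @param gain_threshold,amp_threshold see [classify_segment()].
#' @param max_gap_probes largest probe gap bridged when merging adjacent
#'   same-class calls; default `min_probes - 1` (a gap that could not have
#'   been a retained segment).  Set to `-1` to disable merging.
#' @return `data.frame` of class `cnv_calls`: segment columns plus
#'   `sample_id` and `cnv_class`.
#' @export
call_sample <- function(segments, sample_id, min_probes = 5L,
                        min_abs_mean = 0.25, gain_threshold = 0.25,
                        amp_threshold = 1.0, max_gap_probes = min_probes - 1L) {
  kept <- retain_segments(segments, min_probes, min_abs_mean)
  kept$sample_id <- rep(as.character(sample_id), nrow(kept))
  kept$cnv_class <- if (nrow(kept)) {
    classify_segment(kept$mean_log2, gain_threshold, amp_threshold)
  } else character()
  out <- kept[kept$cnv_class != "unchanged", , drop = FALSE]
  out <- merge_adjacent_calls(out, max_gap_probes)
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

# merge same-class calls on one chromosome whose probe gap is <= max_gap
merge_adjacent_calls <- function(calls, max_gap) {
  if (nrow(calls) < 2 || max_gap < 0) return(calls)
  calls <- calls[order(calls$chrom, calls$start_bp), , drop = FALSE]
  prev <- calls[-nrow(calls), ]
  cur <- calls[-1, ]
  joinable <- c(FALSE, prev$chrom == cur$chrom &
                  prev$cnv_class == cur$cnv_class &
                  cur$first_probe_index - prev$last_probe_index - 1L <= max_gap)
  grp <- cumsum(!joinable)
  merged <- lapply(split(calls, grp), function(g) {
    if (nrow(g) == 1) return(g)
    out <- g[1, , drop = FALSE]
    out$last_probe_index <- g$last_probe_index[nrow(g)]
    out$end_bp <- g$end_bp[nrow(g)]
    out$n_probes <- sum(g$n_probes)
    out$mean_log2 <- sum(g$mean_log2 * g$n_probes) / sum(g$n_probes)
    out$sse <- sum(g$sse)
    out
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}
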