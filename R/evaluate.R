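#' Evaluate recovery of implanted recurrent regions from cohort calls
#'
#' For each recurrent truth region of a simulated cohort, compares the
#' realized carriage (which samples truly carry it) against the calls:
#' a carrying sample counts as detected when one of its calls of the
#' region's class (amplification also satisfying gain, deletion satisfying
#' loss) overlaps the region, and as boundary-accurate when that call's
#' probe boundaries lie within `tolerance_probes` of the truth boundaries.
#' Also reports the region's detected cohort frequency, the maximum
#' per-class count over the minimal common regions inside the truth span.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param calls combined cohort calls (with `first_probe_index` /
#'   `last_probe_index` columns, as produced by [call_sample()] on
#'   [segment_sample()] output).
#' @param tolerance_probes allowed breakpoint deviation in probes (default 2).
#' @return `data.frame`, one row per recurrent region: `chrom`, `start`,
#'   `end`, `cnv_class`, `penetrance`, `n_carrying`, `realized_carriage`,
#'   `n_detected`, `n_boundary_accurate`, `boundary_hit_rate`,
#'   `detected_freq`.
#' @export
evaluate_recovery <- function(cohort, calls, tolerance_probes = 2L) {
  stopifnot(inherits(cohort, "cohort_sim"))
  spec <- cohort$recurrent_spec
  layout <- cohort$layout
  n_samples <- length(cohort$sample_ids)
  effective <- list(gain = c("gain", "amplification"),
                    loss = c("loss", "deletion"),
                    amplification = "amplification", deletion = "deletion")
  regions <- minimal_common_regions(calls, n_samples = n_samples)

  rows <- lapply(seq_len(nrow(spec)), function(i) {
    ch <- spec$chrom[i]
    pos <- layout$pos[layout$chrom == ch]
    truth_first <- min(which(pos >= spec$start[i])) - 1L   # 0-based
    truth_last <- max(which(pos <= spec$end[i])) - 1L
    carriers <- cohort$sample_ids[cohort$carriage[, i]]
    cls <- effective[[spec$cnv_class[i]]]
    detected <- 0L
    accurate <- 0L
    for (s in carriers) {
      cand <- calls[calls$sample_id == s & calls$chrom == ch &
                    calls$cnv_class %in% cls &
                    calls$start_bp <= spec$end[i] & calls$end_bp >= spec$start[i], ,
                    drop = FALSE]
      if (nrow(cand) == 0L) next
      detected <- detected + 1L
      ov <- pmin(cand$end_bp, spec$end[i]) - pmax(cand$start_bp, spec$start[i])
      best <- cand[which.max(ov), ]
      if (abs(best$first_probe_index - truth_first) <= tolerance_probes &&
          abs(best$last_probe_index - truth_last) <= tolerance_probes) {
        accurate <- accurate + 1L
      }
    }
    in_span <- regions$chrom == ch & regions$start_bp <= spec$end[i] &
      regions$end_bp >= spec$start[i]
    det_freq <- if (any(in_span)) {
      max(regions[[paste0("freq_", spec$cnv_class[i])]][in_span])
    } else 0
    data.frame(chrom = ch, start = spec$start[i], end = spec$end[i],
               cnv_class = spec$cnv_class[i], penetrance = spec$penetrance[i],
               n_carrying = length(carriers),
               realized_carriage = length(carriers) / n_samples,
               n_detected = detected, n_boundary_accurate = accurate,
               boundary_hit_rate = if (length(carriers)) accurate / length(carriers) else NA_real_,
               detected_freq = det_freq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run preprocessing, segmentation and calling for every cohort sample
#'
#' Convenience driver used by recovery studies: applies
#' [preprocess_sample()], [segment_sample()] and [call_sample()] to each
#' sample of a simulated cohort and row-binds the calls.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ... passed on to [preprocess_sample()].
#' @return combined `cnv_calls` for the cohort.
#' @export
call_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort_sim"))
  calls <- lapply(cohort$sample_ids, function(s) {
    norm <- preprocess_sample(cohort$samples[[s]], ...)
    call_sample(segment_sample(norm), s)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
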