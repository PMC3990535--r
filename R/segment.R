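#' Optimal k-segment partition by least-squares dynamic programming
#'
#' Exact minimization of the within-segment sum of squared deviations from
#' segment means over all partitions of an ordered series into `k`
#' contiguous segments (O(k n^2) recursion on prefix sums).  Among partitions
#' tying on SSE the lexicographically smallest breakpoint vector is returned.
#'
#' @param series numeric vector (one chromosome's ordered log2 ratios).
#' @param k number of segments, `1 <= k <= length(series)`.
#' @return list with `breakpoints` (1-based indices of segment last probes,
#'   excluding the final probe; length `k - 1`) and `sse` (total squared
#'   error of the optimal partition).
#' @export
best_partition_sse <- function(series, k) {
  series <- as.numeric(series)
  n <- length(series)
  if (n == 0L) stop("empty series")
  if (k < 1 || k > n) stop("k must be in 1..length(series)")
  res <- .dp_segment_all(series, as.integer(k))
  list(breakpoints = res$breaks[[k]], sse = res$sse[[k]])
}

#' Estimate probe-level noise from first differences
#'
#' Robust sd estimate `MAD(diff(x)) / sqrt(2)` (MAD scaled to the normal,
#' i.e. divided by 0.6745): consecutive-probe differences are insensitive to
#' the segment structure itself.
#'
#' @param series numeric vector.
#' @return estimated per-probe noise sd.
#' @export
estimate_noise_sd <- function(series) {
  if (length(series) < 3) return(NA_real_)
  mad(diff(as.numeric(series))) / sqrt(2)
}

#' Shrink single-probe outliers toward the local median
#'
#' Running-median outlier smoothing of the kind commonly applied to aCGH
#' log2 ratios before change-point segmentation: a probe deviating from the
#' median of its `2*half_window + 1` neighborhood by more than
#' `detect_sd * sigma` is shrunk to that median plus/minus
#' `shrink_sd * sigma`.  Leaves the series untouched when the noise
#' estimate is zero (noise-free data has no outliers to smooth).
#'
#' @param series numeric vector.
#' @param half_window neighborhood half-width in probes.
#' @param detect_sd outlier detection threshold in noise SDs.
#' @param shrink_sd residual offset retained after shrinking, in noise SDs.
#' @param sigma noise sd; default [estimate_noise_sd()].
#' @return smoothed numeric vector.
#' @export
smooth_outliers <- function(series, half_window = 5L, detect_sd = 4,
                            shrink_sd = 2, sigma = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(sigma)) sigma <- estimate_noise_sd(x)
  if (!is.finite(sigma) || sigma <= 0 || n < 2 * half_window + 1) return(x)
  med <- vapply(seq_len(n), function(i) {
    median(x[max(1, i - half_window):min(n, i + half_window)])
  }, 1.0)
  dev <- x - med
  out <- abs(dev) > detect_sd * sigma
  x[out] <- med[out] + sign(dev[out]) * shrink_sd * sigma
  x
}

#' Penalized choice of the number of segments
#'
#' Computes SSE(k) for k = 1..`kmax` and returns the smallest k minimizing
#' `SSE(k) + penalty * k`.  The default penalty is the BIC-like
#' `2 * sigma^2 * log(n)` with `sigma` the [estimate_noise_sd()] estimate.
#'
#' @param series numeric vector.
#' @param penalty per-segment penalty (>= 0); `NULL` for the default.
#' @param kmax largest segment count considered (capped at `length(series)`).
#' @return list: `k` (chosen count), `breakpoints`, `sse` (at `k`),
#'   `sse_by_k`, `penalty`.
#' @export
choose_k <- function(series, penalty = NULL, kmax = 20L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n == 0L) stop("empty series")
  kmax <- as.integer(min(kmax, n))
  if (is.null(penalty)) {
    sigma <- estimate_noise_sd(series)
    if (!is.finite(sigma)) sigma <- 0
    penalty <- 2 * sigma^2 * log(n)
  }
  if (penalty < 0) stop("penalty must be >= 0")
  res <- .dp_segment_all(series, kmax)
  obj <- res$sse + penalty * seq_len(kmax)
  k <- which.min(obj)                      # first = smallest k among ties
  list(k = k, breakpoints = res$breaks[[k]], sse = res$sse[[k]],
       sse_by_k = res$sse, penalty = penalty)
}

#' Segment a normalized log2-ratio track per chromosome
#'
#' Runs the penalized least-squares dynamic program independently on each
#' chromosome's ordered probe series and annotates segments with genomic
#' coordinates from the member probes.  Probes with missing values are
#' dropped (with a warning) before segmentation; chromosomes with no probes
#' are skipped with a warning.
#'
#' @param probes a preprocessed `probe_table` with a `log2ratio` column, or a
#'   plain data.frame with `chrom`, `pos` and `log2ratio`.
#' @param penalty,kmax see [choose_k()].
#' @param smooth apply [smooth_outliers()] per chromosome before the DP
#'   (default `TRUE`); segment means and SSE are always reported on the
#'   original, unsmoothed values.
#' @return `data.frame` of class `segment_table`: `chrom`,
#'   `first_probe_index`/`last_probe_index` (0-based, within-chromosome),
#'   `start_bp`/`end_bp` (1-based inclusive), `n_probes`, `mean_log2`, `sse`.
#' @export
segment_sample <- function(probes, penalty = NULL, kmax = 20L, smooth = TRUE) {
  stopifnot(all(c("chrom", "pos", "log2ratio") %in% names(probes)))
  miss <- !is.finite(probes$log2ratio)
  if (any(miss)) {
    warning(sprintf("dropping %d probes with missing log2 ratios", sum(miss)))
    probes <- probes[!miss, , drop = FALSE]
  }
  out <- list()
  for (ch in unique(probes$chrom)) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    if (nrow(p) == 0L) {
      warning("chromosome ", ch, " has no probes; skipped")
      next
    }
    series <- if (smooth) smooth_outliers(p$log2ratio) else p$log2ratio
    sel <- choose_k(series, penalty = penalty, kmax = kmax)
    ends <- c(sel$breakpoints, nrow(p))
    starts <- c(1L, head(ends, -1L) + 1L)
    means <- mapply(function(a, b) mean(p$log2ratio[a:b]), starts, ends)
    sses <- mapply(function(a, b) {
      v <- p$log2ratio[a:b]; sum((v - mean(v))^2)
    }, starts, ends)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      first_probe_index = starts - 1L,
      last_probe_index = ends - 1L,
      start_bp = p$pos[starts],
      end_bp = p$pos[ends],
      n_probes = ends - starts + 1L,
      mean_log2 = means,
      sse = sses,
      stringsAsFactors = FALSE
    )
  }
  segs <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), first_probe_index = integer(),
    last_probe_index = integer(), start_bp = integer(), end_bp = integer(),
    n_probes = integer(), mean_log2 = numeric(), sse = numeric(),
    stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  class(segs) <- c("segment_table", "data.frame")
  segs
}
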