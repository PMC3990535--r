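#' Per-probe log2 ratio of test over reference channel
#'
#' @param test,ref strictly positive intensity vectors of equal length, or a
#'   `probe_table` as `test` (then `ref` is ignored).
#' @param probe_id optional probe names used in error messages.
#' @return numeric vector of `log2(test/ref)` with attribute `stage = "raw"`.
#' @export
log2_ratio <- function(test, ref = NULL, probe_id = NULL) {
  if (inherits(test, "probe_table")) {
    probe_id <- test$probe_id
    ref <- test$ref_intensity
    test <- test$test_intensity
  }
  stopifnot(length(test) == length(ref))
  bad <- which(!is.finite(test) | !is.finite(ref) | test <= 0 | ref <= 0)
  if (length(bad)) {
    id <- if (is.null(probe_id)) as.character(bad[1]) else probe_id[bad[1]]
    stop(sprintf("non-positive or non-finite intensity at probe %s (and %d more)",
                 id, length(bad) - 1L))
  }
  structure(log2(test / ref), stage = "raw")
}

#' LOESS spatial correction of log2 ratios on the array grid
#'
#' Fits a locally weighted polynomial surface f(grid_x, grid_y) to the log2
#' ratios and subtracts it, removing position-dependent signal non-uniformity
#' across the physical array; the pre-correction global mean is restored so
#' the correction is exactly mean-preserving.
#'
#' @param values log2-ratio vector (stage raw).
#' @param layout probe layout aligned with `values` (source of `grid_x`,
#'   `grid_y`).
#' @param span LOESS span (fraction of probes in each local fit).
#' @param degree local polynomial degree, 1 or 2.
#' @return corrected values, attribute `stage = "spatial_corrected"`.
#' @export
spatial_correct <- function(values, layout, span = 0.3, degree = 2) {
  stopifnot(length(values) == nrow(layout), degree %in% c(1, 2))
  if (!all(is.finite(values))) stop("non-finite log2 ratios")
  n <- length(values)
  if (n < 10) stop("too few probes for a local polynomial surface fit")
  df <- data.frame(v = as.numeric(values), gx = layout$grid_x, gy = layout$grid_y)
  fit <- loess(v ~ gx + gy, data = df, span = span, degree = degree,
               family = "gaussian", surface = "interpolate",
               control = loess.control(trace.hat = "approximate"))
  resid <- df$v - fitted(fit)
  out <- resid - mean(resid) + mean(df$v)
  structure(out, stage = "spatial_corrected")
}

#' q-spline normalization of the test channel onto the reference channel
#'
#' Maps the quantiles of the test-channel log intensities onto the
#' corresponding quantiles of the reference channel through a monotone cubic
#' spline fitted at `n_anchors` evenly spaced quantile anchors
#' (`k/(n_anchors+1)`).  Outside the anchor range the mapping continues
#' linearly with the boundary slope, so genuinely extreme intensities (for
#' example probes inside a high-level amplification) are shifted like their
#' neighbors rather than compressed onto the other channel's extremes.
#' Rank order of the probes is preserved; a global scale difference between
#' the channels (dye bias) is absorbed by the mapping.  If the anchor
#' sequence is degenerate the function falls back to piecewise-linear
#' quantile mapping with a warning.
#'
#' @param test,ref strictly positive intensity vectors.
#' @param n_anchors number of interior quantile anchors, at
#'   `k/(n_anchors+1)`, k = 1..n_anchors; must be >= 4.
#' @return normalized test intensities (same length/order as `test`).
#' @export
qspline_normalize <- function(test, ref, n_anchors = 14L) {
  stopifnot(length(test) == length(ref), n_anchors >= 4)
  if (any(test <= 0) || any(ref <= 0)) stop("intensities must be strictly positive")
  lt <- log2(test)
  lr <- log2(ref)
  p <- seq_len(n_anchors) / (n_anchors + 1)
  xa <- unname(quantile(lt, p, type = 7))
  ya <- unname(quantile(lr, p, type = 7))
  keep <- c(TRUE, diff(xa) > 0)       # collapse tied test-quantile anchors
  xa <- xa[keep]; ya <- ya[keep]
  K <- length(xa)
  out_log <-
    if (K >= 4 && !is.unsorted(ya)) {
      f <- splinefun(xa, ya, method = "hyman")
      out <- f(lt)
      # linear continuation beyond the anchors, with the boundary slope
      # (falling back to the overall secant where the spline flattens)
      secant <- (ya[K] - ya[1]) / (xa[K] - xa[1])
      sl <- f(xa[1], deriv = 1); if (!is.finite(sl) || sl <= 0) sl <- secant
      sr <- f(xa[K], deriv = 1); if (!is.finite(sr) || sr <= 0) sr <- secant
      lo <- lt < xa[1]; hi <- lt > xa[K]
      out[lo] <- ya[1] + sl * (lt[lo] - xa[1])
      out[hi] <- ya[K] + sr * (lt[hi] - xa[K])
      out
    } else {
      warning("degenerate quantile anchors; falling back to piecewise-linear mapping")
      approxfun(xa, ya, rule = 2, ties = "ordered")(lt)
    }
  2^out_log
}

#' Preprocess one sample to a normalized log2-ratio track
#'
#' Chains ratio computation, LOESS spatial correction and q-spline
#' normalization.  `order = "spatial-first"` (default) corrects the spatial
#' surface on raw log2 ratios, folds the correction into the test channel,
#' then q-spline-normalizes the channels; `"qspline-first"` normalizes the
#' intensities first and corrects the spatial surface afterwards.  Both
#' orders end at stage `"normalized"`.
#'
#' @param probes a `probe_table` (layout plus `test_intensity`,
#'   `ref_intensity`).
#' @param span,degree see [spatial_correct()].
#' @param n_anchors see [qspline_normalize()].
#' @param order `"spatial-first"` or `"qspline-first"`.
#' @param spatial set `FALSE` to skip spatial correction (raw -> normalized).
#' @param center median-center the final log2 ratios (default `TRUE`): with
#'   most of the genome copy-neutral, the median probe is diploid, so
#'   centering anchors the diploid baseline at log2 = 0 as the calling
#'   thresholds assume.
#' @return `probes` with a `log2ratio` column appended and attribute
#'   `stage = "normalized"`.
#' @export
preprocess_sample <- function(probes, span = 0.3, degree = 2, n_anchors = 14L,
                              order = c("spatial-first", "qspline-first"),
                              spatial = TRUE, center = TRUE) {
  order <- match.arg(order)
  stopifnot(inherits(probes, "probe_table"))
  test <- probes$test_intensity
  ref <- probes$ref_intensity
  if (!spatial) {
    r <- log2_ratio(qspline_normalize(test, ref, n_anchors), ref, probes$probe_id)
  } else if (order == "spatial-first") {
    raw <- log2_ratio(test, ref, probes$probe_id)
    sp <- spatial_correct(raw, probes, span = span, degree = degree)
    test_sp <- ref * 2^as.numeric(sp)        # fold correction into test channel
    r <- log2_ratio(qspline_normalize(test_sp, ref, n_anchors), ref)
  } else {
    test_n <- qspline_normalize(test, ref, n_anchors)
    r <- spatial_correct(log2_ratio(test_n, ref, probes$probe_id), probes,
                         span = span, degree = degree)
  }
  r <- as.numeric(r)
  if (center) r <- r - median(r)
  probes$log2ratio <- r
  attr(probes, "stage") <- "normalized"
  probes
}
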