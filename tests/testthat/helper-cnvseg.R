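# shared fixtures and independent oracles, all built in code

tiny_layout <- function(n_probes = 60L, spacing = 2509, seed = 11) {
  make_layout(n_chrom = 1L, chrom_length_bp = n_probes * spacing,
              spacing_bp = spacing, seed = seed)
}

# exhaustive-enumeration oracle for the k-segment least-squares partition:
# tries every breakpoint combination (combn over segment ends)
brute_force_sse <- function(series, k) {
  n <- length(series)
  seg_sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(seg_sse(series))
  combos <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c_i in seq_len(ncol(combos))) {
    ends <- c(combos[, c_i], n)
    starts <- c(1, head(ends, -1) + 1)
    sse <- sum(mapply(function(a, b) seg_sse(series[a:b]), starts, ends))
    if (sse < best) best <- sse
  }
  best
}

# closed-form least-squares plane fit over the array grid; returns the
# fitted (gx, gy) slopes
plane_slopes <- function(values, layout) {
  fit <- stats::lm(values ~ gx + gy,
                   data = data.frame(values = as.numeric(values),
                                     gx = layout$grid_x, gy = layout$grid_y))
  unname(stats::coef(fit)[c("gx", "gy")])
}

# positionwise oracle for cohort recurrence: per-basepair distinct-sample
# counts with class nesting, evaluated at given positions
positionwise_counts <- function(calls, positions, chrom) {
  effective <- list(gain = c("gain", "amplification"),
                    loss = c("loss", "deletion"),
                    amplification = "amplification", deletion = "deletion")
  out <- matrix(0L, length(positions), length(effective),
                dimnames = list(NULL, names(effective)))
  for (cl in names(effective)) {
    out[, cl] <- vapply(positions, function(p) {
      hit <- calls$chrom == chrom & calls$start_bp <= p & calls$end_bp >= p &
        calls$cnv_class %in% effective[[cl]]
      length(unique(calls$sample_id[hit]))
    }, 1L)
  }
  out
}

# direct-summation hypergeometric tail (choose-product ratio); relative
# error vs exact rational arithmetic is at the double-precision level,
# far below the tolerances asserted against it
direct_hyper_tail <- function(k, K, n, N) {
  j <- seq(max(k, max(0, n - (N - K))), min(K, n))
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

fixture_path <- function(name) system.file("extdata", name, package = "cnvseg")
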