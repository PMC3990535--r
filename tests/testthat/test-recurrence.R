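mk_call <- function(chrom, start, end, sample, class) {
  data.frame(chrom = chrom, start_bp = start, end_bp = end,
             sample_id = sample, cnv_class = class, stringsAsFactors = FALSE)
}

test_that("minimal common regions partition overlapping calls correctly", {
  # one sample, one gain call
  r <- minimal_common_regions(mk_call("1", 100, 200, "S1", "gain"), n_samples = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(r$freq_gain, 0.25)

  # two overlapping gains: three atoms with counts 1, 2, 1
  calls <- rbind(mk_call("1", 100, 200, "S1", "gain"),
                 mk_call("1", 150, 250, "S2", "gain"))
  r <- minimal_common_regions(calls)
  expect_equal(r$start_bp, c(100, 150, 201))
  expect_equal(r$end_bp, c(149, 200, 250))
  expect_equal(r$count_gain, c(1L, 2L, 1L))
  expect_equal(r$n_samples_total, rep(2L, 3))

  expect_error(minimal_common_regions(mk_call("1", 200, 100, "S1", "gain")),
               "start_bp")
})

test_that("amplification nests into gain and deletion into loss when counting", {
  calls <- rbind(mk_call("1", 100, 300, "S1", "amplification"),
                 mk_call("1", 100, 300, "S2", "gain"),
                 mk_call("1", 500, 600, "S1", "deletion"))
  r <- minimal_common_regions(calls)
  expect_equal(r$count_gain[1], 2L)           # amplification counts as gain
  expect_equal(r$count_amplification[1], 1L)
  expect_equal(r$count_loss[2], 1L)           # deletion counts as loss
  expect_equal(r$count_deletion[2], 1L)
  expect_true(all(r$count_gain >= r$count_amplification))
  expect_true(all(r$count_loss >= r$count_deletion))
})

test_that("region counts match a positionwise brute-force sweep on random cohorts", {
  set.seed(40)
  for (rep_i in 1:25) {
    n_s <- sample(2:5, 1)
    calls <- do.call(rbind, lapply(seq_len(n_s), function(s) {
      n_c <- sample(0:4, 1)
      if (n_c == 0) return(NULL)
      start <- sample(1:500, n_c)
      width <- sample(10:200, n_c, replace = TRUE)
      mk_call(sample(c("1", "2"), n_c, replace = TRUE), start, start + width,
              paste0("S", s),
              sample(c("gain", "loss", "amplification", "deletion"), n_c,
                     replace = TRUE))
    }))
    if (is.null(calls) || nrow(calls) == 0) next
    r <- minimal_common_regions(calls, n_samples = n_s)
    # counts constant over each region and equal to the per-position oracle
    for (i in sample(nrow(r), min(nrow(r), 10))) {
      pos <- unique(round(seq(r$start_bp[i], r$end_bp[i], length.out = 3)))
      oracle <- positionwise_counts(calls, pos, r$chrom[i])
      for (cl in c("gain", "loss", "amplification", "deletion")) {
        expect_true(all(oracle[, cl] == r[[paste0("count_", cl)]][i]),
                    info = sprintf("rep %d region %d class %s", rep_i, i, cl))
      }
    }
    # conservation: summed region width x gain count equals the total bp
    # covered by each sample's (gain u amplification) calls
    lhs <- sum((r$end_bp - r$start_bp + 1) * r$count_gain)
    rhs <- sum(vapply(unique(calls$sample_id), function(s) {
      g <- calls[calls$sample_id == s &
                 calls$cnv_class %in% c("gain", "amplification"), ]
      if (nrow(g) == 0) return(0)
      sum(GenomicRanges::width(GenomicRanges::reduce(GenomicRanges::GRanges(
        g$chrom, IRanges::IRanges(g$start_bp, g$end_bp)))))
    }, 1.0))
    expect_equal(lhs, rhs)
    # no two adjacent output regions share identical count vectors
    key <- paste(r$count_gain, r$count_loss, r$count_amplification, r$count_deletion)
    adjacent <- r$chrom[-1] == r$chrom[-nrow(r)] &
      r$start_bp[-1] == r$end_bp[-nrow(r)] + 1
    expect_false(any(adjacent & key[-1] == key[-nrow(r)]))
  }
})

test_that("aggregation is independent of sample input order", {
  set.seed(41)
  calls <- rbind(mk_call("1", c(10, 50, 120), c(100, 200, 300),
                         c("S1", "S2", "S3"), c("gain", "amplification", "loss")),
                 mk_call("2", c(5, 5), c(60, 80), c("S1", "S3"),
                         c("deletion", "loss")))
  r1 <- minimal_common_regions(calls)
  r2 <- minimal_common_regions(calls[sample(nrow(calls)), ])
  expect_equal(r1, r2)
})

test_that("recurrence thresholds are inclusive at 50% and 20%", {
  regions <- minimal_common_regions(rbind(
    mk_call("1", 100, 200, "S1", "gain"),
    mk_call("1", 100, 200, "S2", "gain"),
    mk_call("2", 100, 200, "S1", "amplification")), n_samples = 4)
  # gain at exactly 2/4 = 50% -> recurrent (inclusive)
  rec <- recurrent_regions(regions)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$freq_gain, 0.5)
  # 0.45 excluded at the 50% bound
  regions9 <- minimal_common_regions(rbind(
    do.call(rbind, lapply(1:9, function(i) mk_call("1", 1, 50, paste0("S", i), "gain")))),
    n_samples = 20)
  expect_equal(nrow(recurrent_regions(regions9)), 0L)

  # amplification at exactly 1/4 = 25% >= 20% -> listed; 15% excluded
  amp <- class_frequency_table(regions, "amplification", 0.2)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$frequency_pct, 25)
  regions_low <- minimal_common_regions(rbind(
    do.call(rbind, lapply(1:3, function(i) mk_call("1", 1, 50, paste0("S", i), "amplification")))),
    n_samples = 20)
  expect_equal(nrow(class_frequency_table(regions_low, "amplification", 0.2)), 0L)
  # an amplified region counts toward gain frequency on the same span
  expect_equal(regions_low$freq_gain, regions_low$freq_amplification)

  expect_error(recurrent_regions(regions, threshold = 1.5), "threshold")
})

test_that("a synthetic cohort's implanted regions are recovered at the realized carriage", {
  lay <- make_layout(1, 2509 * 300, 2509, seed = 50)
  spec <- data.frame(chrom = "1", start = lay$pos[100], end = lay$pos[180],
                     cnv_class = "gain", penetrance = 0.6)
  co <- simulate_cohort(20, layout = lay, recurrent_spec = spec,
                        private_cnv_rate = 0, noise_sd = 0.15, seed = 51)
  calls <- do.call(rbind, lapply(co$sample_ids, function(s) {
    pt <- co$samples[[s]]
    pt$log2ratio <- log2(pt$test_intensity / pt$ref_intensity)
    call_sample(segment_sample(pt), s)
  }))
  r <- minimal_common_regions(calls, n_samples = 20)
  carried <- sum(co$carriage[, 1])
  in_region <- r$start_bp <= lay$pos[140] & r$end_bp >= lay$pos[140]
  expect_equal(max(r$count_gain[in_region]), carried)
})
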