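test_that("layouts tile chromosomes at the probe spacing and fill the grid uniquely", {
  lay <- make_layout(n_chrom = 1, chrom_length_bp = 2509000, spacing_bp = 2509,
                     seed = 0)
  expect_equal(nrow(lay), 1000L)
  expect_true(all(lay$chrom == "1"))
  expect_equal(formals(make_layout)$spacing_bp, 2509)
  expect_true(all(diff(lay$pos) > 0))
  expect_false(any(duplicated(paste(lay$grid_x, lay$grid_y))))

  lay3 <- make_layout(n_chrom = 3, chrom_length_bp = c(100000, 50000, 251000),
                      spacing_bp = 2509, seed = 1)
  expect_equal(as.integer(table(lay3$chrom)[c("1", "2", "3")]),
               floor(c(100000, 50000, 251000) / 2509))
  for (ch in unique(lay3$chrom)) {
    expect_true(all(diff(lay3$pos[lay3$chrom == ch]) > 0))
  }
})

test_that("layout generation is deterministic under a seed and rejects small grids", {
  a <- make_layout(2, 100000, 2509, seed = 5)
  b <- make_layout(2, 100000, 2509, seed = 5)
  expect_identical(a, b)
  c <- make_layout(2, 100000, 2509, seed = 6)
  expect_false(identical(a$grid_x, c$grid_x))
  expect_error(make_layout(1, 2509000, 2509, grid_dims = c(10, 10)),
               "grid")
})

test_that("truth implantation shifts exactly the overlapped probes", {
  lay <- tiny_layout(200)
  expect_equal(implant_truth(lay, NULL)$shift, numeric(200))

  # region covering probe indices 100..150 (1-based): 51 probes
  reg <- data.frame(chrom = "1", start = lay$pos[100], end = lay$pos[150],
                    cnv_class = "gain")
  tr <- implant_truth(lay, reg)
  expect_equal(sum(tr$shift != 0), 51L)
  expect_true(all(tr$shift[100:150] == 0.4))
  expect_equal(sum(abs(tr$shift)), 51 * 0.4)

  # default amplification/deletion shifts clear the 1.0 calling bound
  amp <- implant_truth(lay, data.frame(chrom = "1", start = 1, end = 10,
                                       cnv_class = "amplification"))
  expect_gt(amp$regions$log2_shift, 1.0)
  del <- implant_truth(lay, data.frame(chrom = "1", start = 1, end = 10,
                                       cnv_class = "deletion"))
  expect_lt(del$regions$log2_shift, -1.0)

  expect_error(implant_truth(lay, rbind(reg,
    data.frame(chrom = "1", start = lay$pos[140], end = lay$pos[160],
               cnv_class = "loss"))), "overlap")
  expect_error(implant_truth(lay, transform(reg, log2_shift = -0.4)), "sign")
})

test_that("channel simulation reproduces the requested log2-ratio model", {
  lay <- tiny_layout(500)
  # noiseless, flat: ratio exactly 0 everywhere
  pt <- simulate_channels(lay, NULL, noise_sd = 0, affinity_sd = 0, seed = 1)
  expect_equal(log2(pt$test_intensity / pt$ref_intensity), numeric(500))
  expect_true(all(pt$test_intensity > 0 & pt$ref_intensity > 0))

  # implanted +1.3 with noise: in-region mean within the CLT bound
  reg <- data.frame(chrom = "1", start = lay$pos[1], end = lay$pos[500],
                    cnv_class = "amplification")
  tr <- implant_truth(lay, reg)
  pt <- simulate_channels(lay, tr, noise_sd = 0.15, seed = 2)
  m <- mean(log2(pt$test_intensity / pt$ref_intensity))
  expect_lt(abs(m - 1.3), 3 * 0.15 / sqrt(500))

  # pure linear grid gradient recovered by the regression oracle
  pt <- simulate_channels(lay, NULL, noise_sd = 0, gradient = c(0.01, 0),
                          affinity_sd = 0, seed = 3)
  sl <- plane_slopes(log2(pt$test_intensity / pt$ref_intensity), lay)
  expect_equal(sl[1], 0.01, tolerance = 1e-9)
  expect_equal(sl[2], 0, tolerance = 1e-9)

  expect_error(simulate_channels(lay, baseline_intensity = 0), "positive")
  expect_error(simulate_channels(lay, noise_sd = -1), "noise_sd")
})

test_that("noise calibration: residuals about the truth shift are centered", {
  lay <- tiny_layout(400)
  reg <- data.frame(chrom = "1", start = lay$pos[100], end = lay$pos[200],
                    cnv_class = "loss")
  tr <- implant_truth(lay, reg)
  for (seed in 1:5) {
    pt <- simulate_channels(lay, tr, noise_sd = 0.2, gradient = c(0, 0),
                            dye_bias = 0, seed = seed)
    resid <- log2(pt$test_intensity / pt$ref_intensity) - tr$shift
    expect_lt(abs(mean(resid)), 4 * 0.2 / sqrt(400))
  }
})

test_that("cohort carriage follows the recurrent-region penetrance", {
  lay <- tiny_layout(100)
  spec1 <- data.frame(chrom = "1", start = lay$pos[10], end = lay$pos[30],
                      cnv_class = "gain", penetrance = 1.0)
  co <- simulate_cohort(20, layout = lay, recurrent_spec = spec1,
                        private_cnv_rate = 0, seed = 1)
  expect_true(all(co$carriage[, 1]))
  expect_true(all(vapply(co$truth, function(t) "gain" %in% t$cnv_class, TRUE)))

  spec2 <- transform(spec1, penetrance = 0.6)
  co <- simulate_cohort(1000, layout = lay, recurrent_spec = spec2,
                        private_cnv_rate = 0, noise_sd = 0, seed = 1)
  p_hat <- mean(co$carriage[, 1])
  ci <- qbinom(c(0.005, 0.995), 1000, 0.6) / 1000   # 99% binomial interval
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])

  # determinism and conservation of shifted probes
  co2 <- simulate_cohort(5, layout = lay, private_cnv_rate = 1, seed = 9,
                         recurrent_spec = spec2)
  co3 <- simulate_cohort(5, layout = lay, private_cnv_rate = 1, seed = 9,
                         recurrent_spec = spec2)
  expect_identical(co2$samples, co3$samples)
  for (s in co2$sample_ids) {
    tr <- implant_truth(lay, co2$truth[[s]])
    n_overlap <- sum(vapply(seq_len(nrow(tr$regions)), function(i) {
      sum(lay$pos >= tr$regions$start[i] & lay$pos <= tr$regions$end[i])
    }, 1L))
    expect_equal(sum(tr$shift != 0), n_overlap)
  }
})

test_that("qPCR simulation is the generative inverse of the 2^-dCt pipeline", {
  tab <- simulate_qpcr(6.61, ct_sd = 0, sample_sd = 0, seed = 1)
  expect_equal(nrow(tab), 40L)          # 26 tumors + 14 controls
  expect_true(all(c("ct_rep1", "ct_rep2", "ct_rep3") %in% names(tab)))
  res <- qpcr_analyze(tab)
  expect_equal(res$genes$fold, 6.61, tolerance = 1e-12)

  tab1 <- simulate_qpcr(1.0, ct_sd = 0, sample_sd = 0, seed = 2)
  res1 <- qpcr_analyze(tab1)
  expect_equal(res1$genes$mean_tumor, res1$genes$mean_control, tolerance = 1e-12)

  expect_error(simulate_qpcr(-1), "positive")
  expect_error(simulate_qpcr(0), "positive")
})
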