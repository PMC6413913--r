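test_that("exact piecewise input recovers the planted breakpoint to one grid point", {
  rec <- piecewise_recording(break_vo2 = 2000, slope_lo = 0.85, slope_hi = 1.20,
                             by = 20)
  v <- detect_vat_vslope(rec)
  expect_true(v$reliable)
  expect_lte(abs(v$vo2_at_vat - 2000), 20)
  expect_equal(v$slope_below, 0.85, tolerance = 1e-6)
  expect_equal(v$slope_above, 1.20, tolerance = 1e-6)
  # agrees with the brute-force lm()-per-split oracle
  oracle <- brute_vat(rec$vo2_ml_min, rec$vco2_ml_min)
  expect_lte(abs(v$vo2_at_vat - oracle$vo2_at_vat), 20)
  expect_equal(v$sse, oracle$sse, tolerance = 1e-6)
})

test_that("perfectly linear single-slope input is declared unreliable", {
  vo2 <- seq(1000, 3000, by = 25)
  rec <- data.frame(t_s = seq_along(vo2) * 2, vo2_ml_min = vo2,
                    vco2_ml_min = 0.9 * vo2, ve_l_min = vo2 / 40)
  v <- detect_vat_vslope(rec)
  expect_false(v$reliable)
})

test_that("noisy breakpoints are recovered within 5% median error over seeded replicates", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    rec <- piecewise_recording(noise_sd = 0.01 * (0.85 * 1000 + 1.2 * 1000))
    v <- detect_vat_vslope(rec)
    abs(v$vo2_at_vat - 2000) / 2000
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("too few breaths raise an insufficient-data error", {
  rec <- piecewise_recording(vo2_from = 1000, vo2_to = 1200, by = 20)
  expect_error(detect_vat_vslope(rec), "insufficient data")
})
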