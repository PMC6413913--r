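sim_rec <- function(seed = 3, ...) {
  simulate_cpet(subject_profile(id = "t", sex = "male"), seed = seed, ...)
}

test_that("a constant VE column yields max VE equal to that constant", {
  vo2 <- seq(1000, 3000, by = 20)
  rec <- cpet_recording(data.frame(
    t_s = seq_along(vo2) * 2, vo2_ml_min = vo2,
    vco2_ml_min = ifelse(vo2 <= 2000, 0.85 * vo2, 1700 + 1.2 * (vo2 - 2000)),
    ve_l_min = rep(50, length(vo2)), rf_per_min = rep(30, length(vo2))),
    meta = list(mass_kg = 70, incremental_start_s = 0))
  f <- extract_features(rec)
  expect_equal(unname(f["max_ve"]), 50)
})

test_that("any valid recording yields a complete 51-vector in registry order", {
  f <- extract_features(sim_rec())
  expect_equal(length(f), 51L)
  expect_equal(names(f), feature_registry()$name)
  expect_false(anyNA(f))
})

test_that("the first-minute VO2-vs-time slope matches the generating line", {
  t <- seq(1, 59.5, by = 1.5)
  vo2 <- 300 + 200 * (t / 60)
  rec <- cpet_recording(data.frame(
    t_s = t, vo2_ml_min = vo2, vco2_ml_min = 0.85 * vo2,
    ve_l_min = vo2 / 40), meta = list(mass_kg = 70, incremental_start_s = 0))
  f <- suppressWarnings(extract_features(rec))
  expect_equal(unname(f["slope_vo2_min1"]), 200, tolerance = 0.01)
})

test_that("standardization has the closed-form behavior and is exactly invertible", {
  expect_equal(unname(standardize(cbind(f = c(1, 2, 3)))$values[, 1]),
               c(-1, 0, 1))
  set.seed(4)
  m <- matrix(rnorm(20 * 51, mean = 5, sd = 3), 20, 51,
              dimnames = list(NULL, paste0("f", 1:51)))
  std <- standardize(m)
  expect_true(all(abs(colMeans(std$values)) < 1e-10))
  expect_true(all(abs(apply(std$values, 2, sd) - 1) < 1e-10))
  back <- invert_scaler(std$values, std$scaler)
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("feature extraction is deterministic and scale-equivariant in VE", {
  rec <- sim_rec(seed = 8)
  f1 <- extract_features(rec)
  expect_identical(f1, extract_features(rec))
  rec2 <- rec
  rec2$breaths$ve_l_min <- 2 * rec2$breaths$ve_l_min
  rec2$breaths$vt_l <- 2 * rec2$breaths$vt_l
  f2 <- extract_features(rec2)
  expect_equal(unname(f2["max_ve"]), unname(2 * f1["max_ve"]))
  expect_equal(unname(f2["max_ve_vo2"]), unname(2 * f1["max_ve_vo2"]),
               tolerance = 1e-9)
  expect_equal(unname(f2["slope_vco2_ve"]), unname(f1["slope_vco2_ve"] / 2),
               tolerance = 1e-9)
  expect_equal(unname(f2["max_vo2"]), unname(f1["max_vo2"]))
})

test_that("areas A and B sum to the total area of the VO2-vs-VCO2 curve", {
  rec <- sim_rec(seed = 12)
  f <- extract_features(rec)
  b <- rec$breaths[rec$breaths$t_s >= rec$meta$incremental_start_s, ]
  ord <- order(b$vco2_ml_min)
  x <- b$vco2_ml_min[ord] / 1000
  y <- b$vo2_ml_min[ord] / 1000
  total <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  expect_equal(unname(f["area_a"] + f["area_b"]), total, tolerance = 1e-8)
})

test_that("relative VAT time lies strictly inside (0, 1) when the VAT is reliable", {
  for (s in c(2, 5, 9)) {
    f <- extract_features(sim_rec(seed = s))
    expect_gt(unname(f["rel_time_vat"]), 0)
    expect_lt(unname(f["rel_time_vat"]), 1)
  }
})
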