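test_that("noiseless CPET has a non-decreasing VO2 ramp and a single modeled RER crossing", {
  prof <- subject_profile(id = "a", sex = "male")
  rec <- simulate_cpet(prof, seed = 1, noise = cpet_noise(0, 0, 0, 0, 0))
  expect_true(all(diff(rec$breaths$vo2_ml_min) >= -1e-9))
  rer <- rec$breaths$vco2_ml_min / rec$breaths$vo2_ml_min
  crossings <- sum(diff(rer >= 1) == 1)
  expect_equal(crossings, 1L)
  # recording ends when modeled HR reaches hr_max
  expect_lte(max(rec$breaths$hr_bpm), prof$hr_max + 1e-9)
})

test_that("treadmill speed follows the +1 km/h per minute schedule", {
  proto <- protocol_spec(speed_start = 5, speed_increment = 1)
  rec <- simulate_cpet(subject_profile(), protocol = proto, seed = 2)
  b <- rec$breaths
  t0 <- rec$meta$incremental_start_s
  for (k in 1:5) {
    sel <- b$t_s > t0 + 60 * (k - 1) & b$t_s <= t0 + 60 * k
    expect_true(all(abs(b$speed_kmh[sel] - (5 + k)) < 1e-9))
  }
  expect_equal(rec$meta$schedule$speed_kmh,
               5 + rec$meta$schedule$minute)
})

test_that("V-slope detection on a low-noise simulated test recovers the planted VAT within 5%", {
  prof <- subject_profile(id = "v", sex = "female", vo2max_true = 2600,
                          vat_fraction = 0.65)
  rec <- simulate_cpet(prof, seed = 7,
                       noise = cpet_noise(0.005, 0.005, 0.005, 0.01, 0.005))
  v <- detect_vat_vslope(rec)
  expect_true(v$reliable)
  expect_lt(abs(v$vo2_at_vat - 0.65 * 2600) / (0.65 * 2600), 0.05)
})

test_that("invalid protocol increments are rejected", {
  expect_error(protocol_spec(speed_increment = 0), "invalid protocol")
  expect_error(protocol_spec(grade_increment_pct = -1), "invalid protocol")
})

test_that("Wingate summaries follow the curve definitions", {
  flat <- simulate_wingate(shape = list(peak_w = 500, end_w = 500, peak_time_s = 0))
  expect_equal(flat$pp, 500)
  expect_equal(flat$mp, 500)
  expect_equal(flat$fatigue, 0)

  ramp <- simulate_wingate(shape = list(peak_w = 800, end_w = 400, peak_time_s = 0))
  expect_equal(ramp$pp, 800)
  expect_equal(ramp$mp, 600)       # closed-form average of the linear ramp
  expect_equal(ramp$fatigue, 50)   # 100 * (800 - 400) / 800

  expect_equal(ramp$resistance, 0.075)
  expect_error(simulate_wingate(shape = list(peak_w = -5)), "invalid shape")
})

test_that("fatigue index is invariant to uniform scaling of the power curve", {
  a <- simulate_wingate(shape = list(peak_w = 900, end_w = 500))
  b <- simulate_wingate(shape = list(peak_w = 1800, end_w = 1000))
  expect_equal(a$fatigue, b$fatigue)
  expect_equal(b$pp, 2 * a$pp)
})

test_that("cohort size and sex counts match the request", {
  coh <- suppressMessages(
    simulate_cohort(88, seed = 42, sex_counts = c(female = 36, male = 52)))
  expect_equal(nrow(coh$manifest), 88L)
  expect_equal(sum(coh$manifest$sex == "female"), 36L)
  expect_equal(sum(coh$manifest$sex == "male"), 52L)
  expect_error(simulate_cohort(5), "too small")
})

test_that("noiseless planted outcomes equal the linear combination exactly", {
  gen <- generative_spec(noise_sd = 0)
  coh <- suppressMessages(simulate_cohort(15, gen = gen, seed = 5))
  z <- coh$features_std[, gen$signal_features]
  expect_equal(coh$manifest$pp_w,
               as.numeric(gen$intercept + z %*% gen$coefficients),
               tolerance = 1e-12)
})

test_that("least squares on the true design recovers planted coefficients within 10%", {
  gen0 <- generative_spec(signal_features = c("max_rf", "rel_time_vat", "max_vo2"),
                          coefficients = c(80, -50, 60), intercept = 600,
                          noise_sd = 0)
  coh0 <- suppressMessages(simulate_cohort(200, gen = gen0, seed = 31))
  sd_y <- sd(coh0$manifest$pp_w)
  gen <- generative_spec(signal_features = gen0$signal_features,
                         coefficients = gen0$coefficients, intercept = 600,
                         noise_sd = 0.05 * sd_y)
  coh <- suppressMessages(simulate_cohort(200, gen = gen, seed = 31))
  fit <- lm(coh$manifest$pp_w ~ coh$features_std[, gen$signal_features])
  est <- unname(coef(fit)[-1])
  expect_true(all(abs(est - gen0$coefficients) / abs(gen0$coefficients) < 0.10))
})

test_that("the same master seed reproduces the cohort bit-identically", {
  a <- suppressMessages(simulate_cohort(12, seed = 9))
  b <- suppressMessages(simulate_cohort(12, seed = 9))
  expect_identical(a$features, b$features)
  expect_identical(a$manifest, b$manifest)
  d <- suppressMessages(simulate_cohort(12, seed = 10))
  expect_false(identical(a$features, d$features))
})
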