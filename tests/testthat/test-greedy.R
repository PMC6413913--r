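test_that("adjusted R^2 follows the closed form and rejects exhausted degrees of freedom", {
  expect_equal(adjusted_r2(1, 20, 5), 1)
  expect_equal(adjusted_r2(0.9, 35, 3), 1 - 0.1 * 34 / 31)
  expect_equal(round(adjusted_r2(0.9, 35, 3), 5), 0.89032)
  expect_equal(adjusted_r2(0, 10, 0), 0)
  expect_error(adjusted_r2(0.5, 5, 4), "undefined")
})

test_that("stratified splits are disjoint, exhaustive, and balanced within tertiles", {
  sp <- split_stratified(rnorm(10), seed = 1)
  expect_equal(lengths(sp), c(train = 4L, test = 3L, validation = 3L))
  all_idx <- sort(unlist(sp, use.names = FALSE))
  expect_equal(all_idx, 1:10)

  # 30 subjects, tertiles of 10: each tertile contributes 4/3/3
  strata <- 1:30
  sp <- split_stratified(strata, seed = 2)
  tert <- list(1:10, 11:20, 21:30)
  for (tt in tert) {
    expect_equal(sum(sp$train %in% tt), 4L)
    expect_equal(sum(sp$test %in% tt), 3L)
    expect_equal(sum(sp$validation %in% tt), 3L)
  }
  expect_error(split_stratified(rnorm(5)), "stratification error")
})

test_that("a perfect single predictor is selected first with zero train error", {
  set.seed(11)
  x <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- x[, "f7"]
  run <- greedy_select(x, y)
  expect_equal(run$features[1], "f7")
  expect_equal(run$r2[1], 1, tolerance = 1e-10)
  expect_equal(run$stop_reason, "perfect_fit")
})

test_that("a planted 2-feature signal is found before any nuisance feature and matches best subset", {
  set.seed(21)
  x <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- 2 * x[, "f1"] - 1.5 * x[, "f4"] + rnorm(80, 0, 0.05)
  run <- greedy_select(x, y)
  expect_setequal(run$features[1:2], c("f1", "f4"))
  expect_equal(best_subset(x, y, 2), c("f1", "f4"))
})

test_that("selection stops on an adjusted-R^2 relative drop, returning the pre-drop model", {
  # n = 10, two signal features, one candidate orthogonal to the residual:
  # the third addition gains nothing, so adjusted R^2 falls by > 2% relative.
  set.seed(33)
  n <- 10
  f1 <- rnorm(n); f2 <- rnorm(n); f3 <- rnorm(n)
  y0 <- f1 + f2
  raw <- rnorm(n)
  r <- resid(lm(raw ~ f1 + f2 + f3))       # orthogonal to {1, f1, f2, f3}
  r <- r / sqrt(sum(r^2))
  T0 <- sum((y0 - mean(y0))^2)
  y <- y0 + sqrt(T0 / 9) * r               # R^2 of the 2-term fit = 0.9
  x <- cbind(f1 = f1, f2 = f2, f3 = f3)

  # independent check of the premise via lm()
  r2_of <- function(fit, y) 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  adj2 <- adjusted_r2(r2_of(lm(y ~ f1 + f2), y), n, 2)
  adj3 <- adjusted_r2(r2_of(lm(y ~ f1 + f2 + f3), y), n, 3)
  expect_lt(adj3, 0.98 * adj2)

  run <- greedy_select(x, y)
  expect_equal(run$stop_reason, "adjusted_r2_drop")
  expect_equal(length(run$features), 2L)
  expect_setequal(run$features, c("f1", "f2"))
})

test_that("greedy train SSE never increases as features are added", {
  set.seed(13)
  x <- matrix(rnorm(60 * 15), 60, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- x[, 1] - x[, 2] + rnorm(60, 0, 2)
  run <- greedy_select(x, y, termination = 1, max_features = 10)  # no early stop
  expect_true(all(diff(run$r2) >= -1e-12))
})

test_that("consensus fitting satisfies the OLS identities and recovers planted models exactly", {
  set.seed(17)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, "f2"]
  eq <- fit_consensus(x, y, "f2")
  expect_equal(eq$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(eq$coefficients["f2"]), 1, tolerance = 1e-10)

  z <- standardize(x)$values
  y2 <- 3 + 2 * z[, "f1"] - z[, "f3"]
  eq2 <- fit_consensus(z, y2, c("f1", "f3"))
  expect_equal(eq2$intercept, mean(y2), tolerance = 1e-8)  # mean-zero regressors
  expect_equal(unname(eq2$coefficients), c(2, -1), tolerance = 1e-8)

  expect_error(fit_consensus(cbind(a = x[, 1], b = x[, 1]), y, c("a", "b")),
               "rank-deficient")
})

test_that("equation prediction is the plain linear form over named features", {
  eq <- predictor_equation("pp_w", intercept = 638.4,
                           coefficients = c(max_ve = 170.3, max_rf = -43.5))
  v <- c(max_ve = 1, max_rf = 0, max_vo2 = 2)
  expect_equal(predict(eq, v), 638.4 + 170.3)
  expect_error(predict(eq, c(max_ve = 1)), "max_rf")
})

test_that("evaluation metrics match hand-computed values", {
  perfect <- evaluate_predictions(c(3, 1, 2), c(3, 1, 2))
  expect_equal(perfect$spearman_r, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pct_err_mean, 0)

  m <- evaluate_predictions(c(100, 200, 300), c(110, 190, 330))
  expect_equal(round(m$rmse, 4), 19.1485)          # sqrt((100+100+900)/3)
  expect_equal(round(m$pct_err_mean, 4), 8.3333)   # mean(10, 5, 10)
  expect_equal(m$spearman_r, 1)

  rev <- evaluate_predictions(c(1, 2, 3, 4), c(9, 7, 5, 3))
  expect_equal(rev$spearman_r, -1)
})

test_that("stability voting ranks planted features above a correlated nuisance", {
  set.seed(19)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  nuis <- 0.6 * f1 + sqrt(1 - 0.36) * rnorm(n)
  x <- cbind(f1 = f1, f2 = f2, nuis = nuis,
             matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("g", 1:7))))
  y <- 2 * f1 + 1.5 * f2 + rnorm(n, 0, 1.2)
  st <- stability_select(x, y, n_runs = 50, seed = 5)
  expect_gt(st$frequency["f1"], st$frequency["nuis"])
  expect_gt(st$frequency["f2"], st$frequency["nuis"])
  expect_true(all(c("f1", "f2") %in% st$consensus))

  # a noiseless single-feature signal is selected in every run
  y1 <- 4 * f2
  st1 <- stability_select(x, y1, n_runs = 20, seed = 6)
  expect_equal(unname(st1$frequency["f2"]), 1)
})

test_that("protocol defaults follow the published procedure sizes", {
  expect_equal(eval(formals(run_full_protocol)$n_outer), 100)
  expect_equal(eval(formals(run_full_protocol)$n_runs), 1000)
  expect_equal(eval(formals(stability_select)$n_runs), 1000)
  expect_equal(eval(formals(split_stratified)$fractions),
               c(train = 0.4, test = 0.3, validation = 0.3))
})

test_that("a noiseless planted cohort validates perfectly in every protocol repeat", {
  gen <- generative_spec(signal_features = c("max_rf", "rel_time_vat"),
                         coefficients = c(90, -45), intercept = 600,
                         noise_sd = 0)
  coh <- suppressMessages(simulate_cohort(60, gen = gen, seed = 23))
  res <- run_full_protocol(coh$features, coh$manifest$pp_w, n_outer = 3,
                           n_runs = 10, seed = 2)
  expect_true(all(abs(res$per_repeat$spearman_r - 1) < 1e-8))
  expect_true(all(res$per_repeat$rmse < 1e-6))
})
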