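# Greedy forward feature-selection regression with adjusted-R^2 stopping,
# stability voting over repeated random splits, stratified splitting, and
# cross-validated evaluation.

#' Adjusted coefficient of determination
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return `1 - (1 - r2) * (n - 1) / (n - p - 1)`.
#' @export
#' @examples
#' adjusted_r2(0.9, 35, 3)
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R^2 undefined: need n > p + 1 (n = ", n,
                       ", p = ", p, ")")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Equal-size tertile (or k-tile) labels by rank.
ntile <- function(x, k) {
  ceiling(k * rank(x, ties.method = "first") / length(x))
}

#' Stratified train/test/validation split
#'
#' Splits indices `1..n` into disjoint, exhaustive subsets matching the given
#' fractions.  Stratification cuts `strata` (typically the VO2max feature)
#' into `n_strata` equal-size groups by rank, and allocates within each group
#' by largest-remainder rounding (remainder ties resolved in the order the
#' fractions are given), so each stratum's subset proportions deviate from the
#' global fractions by at most one subject.
#'
#' @param strata Numeric vector (one value per subject) to stratify on, or a
#'   factor of precomputed groups.
#' @param fractions Named fractions summing to 1
#'   (default `c(train = 0.4, test = 0.3, validation = 0.3)`).
#' @param n_strata Number of strata when `strata` is numeric (default 3).
#' @param seed Optional integer seed.
#' @return Named list of integer index vectors, one per fraction.
#' @export
#' @examples
#' split_stratified(rnorm(10), seed = 1)
split_stratified <- function(strata,
                             fractions = c(train = 0.4, test = 0.3, validation = 0.3),
                             n_strata = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(strata)
  if (n < 10) stop("stratification error: need n >= 10")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  g <- if (is.factor(strata)) as.integer(strata) else ntile(strata, n_strata)
  if (min(table(g)) < 1) stop("stratification error: empty stratum")
  out <- stats::setNames(vector("list", length(fractions)), names(fractions))
  out[] <- list(integer(0))
  for (s in unique(g)) {
    idx <- sample(which(g == s))
    ns <- length(idx)
    want <- fractions * ns
    base <- floor(want)
    rem <- want - base
    extra <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")
    add <- integer(length(fractions))
    leftover <- ns - sum(base)
    if (leftover > 0) add[extra[seq_len(leftover)]] <- 1L
    sizes <- base + add
    pos <- 1L
    for (j in seq_along(fractions)) {
      if (sizes[j] > 0) {
        out[[j]] <- c(out[[j]], idx[pos:(pos + sizes[j] - 1L)])
        pos <- pos + sizes[j]
      }
    }
  }
  lapply(out, sort)
}

#' Greedy forward feature selection by least-squares prediction error
#'
#' Starting from the intercept-only model, each iteration fits an ordinary
#' least-squares regression of the outcome on the current features plus each
#' remaining candidate and adds the candidate minimizing the training sum of
#' squared prediction errors (implemented by successive orthogonalization,
#' which yields the same SSE as refitting).  The test-set Spearman correlation
#' of each step's model is recorded for monitoring.  Selection stops when the
#' best candidate's adjusted R^2 falls more than `termination` below the
#' current model's (relative drop by default: stop when
#' `adj_new < (1 - termination) * adj_current`; `relative = FALSE` uses an
#' absolute drop), when the fit is essentially perfect, when degrees of
#' freedom run out, or at `max_features`.  Candidates that are numerically
#' collinear with the selected design are skipped.
#'
#' @param x_train Standardized training matrix (subjects x features).
#' @param y_train Training outcome vector.
#' @param x_test,y_test Optional test split for per-step Spearman monitoring.
#' @param termination Adjusted-R^2 drop triggering the stop (default 0.02).
#' @param relative Interpret `termination` as a relative drop (default TRUE).
#' @param max_features Hard cap on model size; default `NULL` caps at
#'   `n - 3` so the adjusted R^2 of a further step stays defined.
#' @param outcome Label stored on the returned equation.
#' @return Object of class `selection_run`: list with `features` (ordered
#'   selected names), `adj_r2`, `r2`, `test_spearman` (per step), `stop_reason`
#'   and `equation` (a [predictor_equation()] fit on the training split).
#' @export
greedy_select <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                          termination = 0.02, relative = TRUE,
                          max_features = NULL, outcome = "pp_w") {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  K <- ncol(x_train)
  stopifnot(length(y_train) == n, n > 3)
  if (is.null(max_features)) max_features <- n - 3L
  feat_names <- colnames(x_train)

  # residualize everything on the intercept
  yr <- y_train - mean(y_train)
  Xr <- sweep(x_train, 2, colMeans(x_train), "-")
  col_scale <- sqrt(colSums(Xr^2))
  tss <- sum(yr^2)
  if (tss <= 0) stop("constant outcome")
  sse <- tss
  sel <- integer(0)
  adj_seq <- r2_seq <- sp_seq <- numeric(0)
  adj_cur <- 0
  stop_reason <- "exhausted_candidates"
  active <- col_scale > 1e-10
  tol <- 1e-10

  step_spearman <- function(sel_idx) {
    if (is.null(x_test) || is.null(y_test)) return(NA_real_)
    fit <- stats::lsfit(x_train[, sel_idx, drop = FALSE], y_train)
    pred <- cbind(1, as.matrix(x_test)[, sel_idx, drop = FALSE]) %*% fit$coefficients
    if (stats::sd(pred) == 0 || stats::sd(y_test) == 0) return(NA_real_)
    stats::cor(as.numeric(pred), y_test, method = "spearman")
  }

  repeat {
    if (length(sel) >= max_features) { stop_reason <- "max_features"; break }
    if (n - length(sel) - 2 < 1) { stop_reason <- "degrees_of_freedom"; break }
    d <- colSums(Xr^2)
    ok <- active & d > (tol * pmax(col_scale^2, 1))
    ok[sel] <- FALSE
    if (!any(ok)) { stop_reason <- "exhausted_candidates"; break }
    red <- rep(-Inf, K)
    red[ok] <- (colSums(Xr[, ok, drop = FALSE] * yr)^2) / d[ok]
    j <- which.max(red)   # ties: lowest registry index
    sse_new <- max(sse - red[j], 0)
    r2_new <- 1 - sse_new / tss
    adj_new <- adjusted_r2(r2_new, n, length(sel) + 1L)
    threshold <- if (relative) (1 - termination) * adj_cur else adj_cur - termination
    if (length(sel) >= 1 && adj_new < threshold) {
      stop_reason <- "adjusted_r2_drop"
      break
    }
    sel <- c(sel, j)
    sse <- sse_new
    adj_cur <- adj_new
    r2_seq <- c(r2_seq, r2_new)
    adj_seq <- c(adj_seq, adj_new)
    sp_seq <- c(sp_seq, step_spearman(sel))
    if (r2_new > 1 - 1e-12) { stop_reason <- "perfect_fit"; break }
    # orthogonalize remaining candidates and the outcome on the chosen column
    v <- Xr[, j]
    dj <- sum(v^2)
    yr <- yr - v * (sum(v * yr) / dj)
    proj <- crossprod(v, Xr) / dj
    Xr <- Xr - tcrossprod(v, as.numeric(proj))
    Xr[, j] <- 0
    active[j] <- FALSE
  }

  fit <- stats::lsfit(x_train[, sel, drop = FALSE], y_train)
  coefs <- fit$coefficients
  eq <- predictor_equation(outcome = outcome, intercept = unname(coefs[1]),
                           coefficients = stats::setNames(unname(coefs[-1]),
                                                          feat_names[sel]))
  structure(list(features = feat_names[sel], adj_r2 = adj_seq, r2 = r2_seq,
                 test_spearman = sp_seq, stop_reason = stop_reason,
                 equation = eq),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat("greedy selection:", length(x$features), "feature(s), stop:",
      x$stop_reason, "\n")
  if (length(x$features)) {
    print(data.frame(feature = x$features, adj_r2 = round(x$adj_r2, 4),
                     test_spearman = round(x$test_spearman, 3)))
  }
  invisible(x)
}

#' Stability voting over repeated random calibration splits
#'
#' Repeats `n_runs` times: re-split the calibration pool into train and test
#' (stratified on `strata` when given, with the train/test fractions keeping
#' their 40/30 ratio), run [greedy_select()], and record the selected
#' features.  The per-feature selection frequency is the fraction of runs
#' selecting it; the consensus set contains features with frequency at or
#' above `threshold`, ordered by frequency (ties by mean selection step, then
#' name).
#'
#' @param x_cal Standardized calibration matrix.
#' @param y_cal Calibration outcome.
#' @param n_runs Number of repeated splits (default 1000).
#' @param threshold Consensus frequency threshold (default 0.5).
#' @param strata Optional numeric stratification variable (one per row), e.g.
#'   raw VO2max.
#' @param fractions Train/test fractions within the calibration pool
#'   (default `c(train = 4/7, test = 3/7)`, the 40/30 split renormalized).
#' @param seed Master seed spawning one stream per run.
#' @param ... Passed to [greedy_select()].
#' @return Object of class `stability_result`: `frequency` (named, sorted),
#'   `mean_step`, `consensus`, `n_runs`.
#' @export
stability_select <- function(x_cal, y_cal, n_runs = 1000, threshold = 0.5,
                             strata = NULL, fractions = c(train = 4 / 7, test = 3 / 7),
                             seed = 1, ...) {
  x_cal <- as.matrix(x_cal)
  n <- nrow(x_cal)
  feat_names <- colnames(x_cal)
  count <- stats::setNames(numeric(ncol(x_cal)), feat_names)
  step_sum <- count
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  if (is.null(strata)) strata <- seq_len(n)  # unstratified: ranks are arbitrary
  for (r in seq_len(n_runs)) {
    sp <- split_stratified(strata, fractions = fractions, seed = run_seeds[r])
    run <- greedy_select(x_cal[sp$train, , drop = FALSE], y_cal[sp$train],
                         x_cal[sp$test, , drop = FALSE], y_cal[sp$test], ...)
    if (length(run$features)) {
      count[run$features] <- count[run$features] + 1
      step_sum[run$features] <- step_sum[run$features] + seq_along(run$features)
    }
  }
  freq <- count / n_runs
  mean_step <- ifelse(count > 0, step_sum / count, Inf)
  ord <- order(-freq, mean_step, feat_names)
  freq <- freq[ord]; mean_step <- mean_step[ord]
  consensus <- names(freq)[freq >= threshold]
  structure(list(frequency = freq, mean_step = mean_step,
                 consensus = consensus, n_runs = n_runs,
                 threshold = threshold),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability selection over", x$n_runs, "runs; consensus:",
      if (length(x$consensus)) paste(x$consensus, collapse = ", ") else "(empty)", "\n")
  print(round(utils::head(x$frequency, 10), 3))
  invisible(x)
}

#' Linear predictor equation (intercept + feature terms)
#'
#' The object produced by selection and consumed by [predict.predictor_equation()]:
#' `outcome = intercept + sum(coefficient * standardized feature)`.
#'
#' @param outcome One of `"pp_w"`, `"mp_w"`, `"pp_w_per_kg"`, `"mp_w_per_kg"`,
#'   `"fatigue_pct"`.
#' @param intercept Intercept in outcome units.
#' @param coefficients Named numeric vector of per-feature coefficients.
#' @param scaler Optional scaler (from [standardize()]) the equation expects
#'   its inputs to be standardized with.
#' @param provenance Optional list (seeds, n_runs, config hash, ...).
#' @return Object of class `predictor_equation`.
#' @export
predictor_equation <- function(outcome, intercept, coefficients,
                               scaler = NULL, provenance = NULL) {
  outcome <- match.arg(outcome, c("pp_w", "mp_w", "pp_w_per_kg", "mp_w_per_kg",
                                  "fatigue_pct"))
  if (is.null(names(coefficients)) && length(coefficients)) {
    stop("coefficients must be named by feature")
  }
  if (anyDuplicated(names(coefficients))) stop("duplicate feature names")
  structure(list(outcome = outcome, intercept = intercept,
                 coefficients = coefficients, scaler = scaler,
                 provenance = provenance),
            class = "predictor_equation")
}

#' @export
print.predictor_equation <- function(x, ...) {
  terms <- paste(sprintf("%+.4g * %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("%s = %.4g %s\n", x$outcome, x$intercept, terms))
  invisible(x)
}

#' Predict an anaerobic outcome from a standardized feature vector
#'
#' @param object A [predictor_equation()].
#' @param newdata Named numeric vector, or matrix/data.frame with feature
#'   columns, already on the standardized scale the equation was fit on.
#' @param ... Unused.
#' @return Numeric predictions (one per row).
#' @export
predict.predictor_equation <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(newdata))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  as.numeric(object$intercept +
               newdata[, need, drop = FALSE] %*% object$coefficients)
}

#' Fit the consensus equation by ordinary least squares
#'
#' @param x_cal Standardized calibration matrix.
#' @param y_cal Calibration outcome.
#' @param features Consensus feature names (nonempty).
#' @param outcome Outcome label.
#' @param scaler Optional scaler carried on the equation.
#' @param provenance Optional provenance list.
#' @return A [predictor_equation()].
#' @export
fit_consensus <- function(x_cal, y_cal, features, outcome = "pp_w",
                          scaler = NULL, provenance = NULL) {
  if (!length(features)) stop("consensus feature set is empty")
  x <- as.matrix(x_cal)[, features, drop = FALSE]
  qrX <- qr(cbind(1, x))
  if (qrX$rank < ncol(x) + 1) {
    dropped <- features[qrX$pivot[seq_len(qrX$rank)][-1] - 1]
    stop("rank-deficient design; offending feature(s): ",
         paste(setdiff(features, dropped), collapse = ", "))
  }
  coefs <- qr.coef(qrX, y_cal)
  predictor_equation(outcome = outcome, intercept = unname(coefs[1]),
                     coefficients = stats::setNames(unname(coefs[-1]), features),
                     scaler = scaler, provenance = provenance)
}

#' Prediction metrics: Spearman correlation, RMSE, percent error
#'
#' Spearman uses average ranks on ties; percent error is
#' `100 * |pred - obs| / obs`, with non-positive observations excluded (with a
#' message).  Constant predictions leave the Spearman correlation `NA`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return Object of class `evaluation_metrics`: `spearman_r`, `rmse`,
#'   `pct_err_mean`, `pct_err_sd`, `n`.
#' @export
#' @examples
#' evaluate_predictions(c(100, 200, 300), c(110, 190, 330))
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  rmse <- sqrt(mean((predicted - observed)^2))
  sp <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) NA_real_ else
    stats::cor(predicted, observed, method = "spearman")
  pos <- observed > 0
  if (any(!pos)) message("excluding ", sum(!pos), " non-positive observation(s) from percent error")
  pe <- 100 * abs(predicted[pos] - observed[pos]) / observed[pos]
  structure(list(spearman_r = sp, rmse = rmse,
                 pct_err_mean = mean(pe), pct_err_sd = stats::sd(pe),
                 n = length(observed)),
            class = "evaluation_metrics")
}

#' Evaluate a predictor equation on a labeled feature set
#'
#' @param equation A [predictor_equation()].
#' @param features Standardized feature matrix.
#' @param observed Observed outcome vector.
#' @return [evaluate_predictions()] result.
#' @export
evaluate_equation <- function(equation, features, observed) {
  evaluate_predictions(observed, predict(equation, features))
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f, RMSE = %.2f, %%error = %.1f +- %.1f (n = %d)\n",
              x$spearman_r, x$rmse, x$pct_err_mean, x$pct_err_sd, x$n))
  invisible(x)
}

#' Full selection-and-validation protocol
#'
#' Repeats `n_outer` times: split the cohort 40/30/30 into train/test/
#' validation stratified on the VO2max feature; standardize features on the
#' calibration pool (train + test) and apply that scaler to the validation set
#' (`paper_faithful = TRUE` standardizes globally before splitting instead);
#' run [stability_select()] with `n_runs` internal re-splits of the
#' calibration pool; fit the consensus equation on the whole calibration pool;
#' evaluate on the held-out validation set.  If a repeat's consensus is empty,
#' the most frequently selected feature is used.
#'
#' @param features Raw (unstandardized) n x 51 feature matrix.
#' @param outcome Outcome vector aligned with `features` rows.
#' @param stage Candidate filter: `"all"` (complete registry, the default),
#'   `"full_test"` (whole-test features only) or `"early_minutes"` (features
#'   from the first four incremental minutes only).
#' @param n_outer Outer validation repeats (default 100).
#' @param n_runs Stability runs per repeat (default 1000).
#' @param fractions Train/test/validation fractions.
#' @param termination Adjusted-R^2 stop threshold for [greedy_select()].
#' @param consensus_threshold Stability frequency threshold.
#' @param paper_faithful Standardize on the full cohort before splitting.
#' @param strata_feature Feature used for stratification (default `max_vo2`).
#' @param outcome_label Label carried on fitted equations.
#' @param max_features Cap on greedy model size per run.
#' @param registry Feature registry (for the stage filter).
#' @param seed Master seed.
#' @return Object of class `protocol_result`: `per_repeat` data.frame
#'   (spearman_r, rmse, pct_err_mean, pct_err_sd, n_features per repeat),
#'   `aggregate` list (means and SDs), `consensus_frequency` (how often each
#'   feature entered a repeat's consensus), `last_equation`, and `config`.
#' @export
run_full_protocol <- function(features, outcome,
                              stage = c("all", "full_test", "early_minutes"),
                              n_outer = 100, n_runs = 1000,
                              fractions = c(train = 0.4, test = 0.3, validation = 0.3),
                              termination = 0.02, consensus_threshold = 0.5,
                              paper_faithful = FALSE, strata_feature = "max_vo2",
                              outcome_label = "pp_w", max_features = 12,
                              registry = feature_registry(), seed = 1) {
  stage <- match.arg(stage)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(outcome))
  if (!strata_feature %in% colnames(features)) {
    stop("stratification feature not present: ", strata_feature)
  }
  keep <- switch(stage,
                 all = registry$name,
                 full_test = registry$name[registry$stage == "full_test"],
                 early_minutes = registry$name[registry$stage == "early_minutes"])
  keep <- intersect(keep, colnames(features))
  # defensive: zero-variance columns cannot be standardized
  sds <- apply(features[, keep, drop = FALSE], 2, stats::sd)
  if (any(!(sds > 0))) {
    message("dropping zero-variance candidate(s): ",
            paste(keep[!(sds > 0)], collapse = ", "))
    keep <- keep[sds > 0]
  }
  strata_all <- features[, strata_feature]

  set.seed(seed)
  outer_seeds <- sample.int(.Machine$integer.max - 1L, n_outer * 2L)
  global_std <- if (paper_faithful) standardize(features[, keep, drop = FALSE]) else NULL

  rows <- vector("list", n_outer)
  consensus_count <- stats::setNames(numeric(length(keep)), keep)
  last_eq <- NULL
  for (r in seq_len(n_outer)) {
    sp <- split_stratified(strata_all, fractions = fractions,
                           seed = outer_seeds[2 * r - 1L])
    cal <- sort(c(sp$train, sp$test))
    if (paper_faithful) {
      z_cal <- global_std$values[cal, , drop = FALSE]
      z_val <- global_std$values[sp$validation, , drop = FALSE]
      scaler <- global_std$scaler
    } else {
      std <- standardize(features[cal, keep, drop = FALSE])
      z_cal <- std$values
      scaler <- std$scaler
      z_val <- apply_scaler(features[sp$validation, keep, drop = FALSE], scaler)
    }
    stab <- stability_select(z_cal, outcome[cal], n_runs = n_runs,
                             threshold = consensus_threshold,
                             strata = strata_all[cal],
                             seed = outer_seeds[2 * r],
                             termination = termination,
                             max_features = max_features,
                             outcome = outcome_label)
    cons <- stab$consensus
    if (!length(cons)) cons <- names(stab$frequency)[1]
    consensus_count[cons] <- consensus_count[cons] + 1
    eq <- fit_consensus(z_cal, outcome[cal], cons, outcome = outcome_label,
                        scaler = scaler)
    met <- evaluate_equation(eq, z_val, outcome[sp$validation])
    rows[[r]] <- data.frame(repeat_id = r, spearman_r = met$spearman_r,
                            rmse = met$rmse, pct_err_mean = met$pct_err_mean,
                            pct_err_sd = met$pct_err_sd,
                            n_features = length(cons))
    last_eq <- eq
  }
  per_repeat <- do.call(rbind, rows)
  aggregate <- list(
    spearman_mean = mean(per_repeat$spearman_r, na.rm = TRUE),
    spearman_sd = stats::sd(per_repeat$spearman_r, na.rm = TRUE),
    rmse_mean = mean(per_repeat$rmse),
    pct_err_mean = mean(per_repeat$pct_err_mean),
    pct_err_sd = mean(per_repeat$pct_err_sd),
    n_features_mean = mean(per_repeat$n_features)
  )
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 consensus_frequency = sort(consensus_count / n_outer,
                                            decreasing = TRUE),
                 last_equation = last_eq,
                 config = list(stage = stage, n_outer = n_outer, n_runs = n_runs,
                               fractions = fractions, termination = termination,
                               consensus_threshold = consensus_threshold,
                               paper_faithful = paper_faithful,
                               outcome = outcome_label, seed = seed)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("protocol (%s, %d outer repeats x %d stability runs):\n",
              x$config$stage, x$config$n_outer, x$config$n_runs))
  cat(sprintf("  validation Spearman r = %.3f (SD %.3f), RMSE = %.1f, %%error = %.1f +- %.1f\n",
              a$spearman_mean, a$spearman_sd, a$rmse_mean, a$pct_err_mean,
              a$pct_err_sd))
  invisible(x)
}
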