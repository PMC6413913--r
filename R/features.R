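# Extraction of the 51 canonical aerobic features from a CPET recording,
# and column standardization of the resulting feature matrix.

roll_mean <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

smoothed_max <- function(x, w) {
  s <- roll_mean(x, w)
  if (all(is.na(s))) max(x) else max(s, na.rm = TRUE)
}

ols_slope <- function(x, y) {
  vx <- x - mean(x); vy <- y - mean(y)
  d <- sum(vx^2)
  if (d <= 0) return(NA_real_)
  sum(vx * vy) / d
}

#' Extract the 51 canonical aerobic features from a CPET recording
#'
#' Direct features are maxima of a centered rolling mean over `window` breaths
#' (breath-by-breath maxima are noise-dominated); the test duration, maximal
#' speed and maximal grade are taken as recorded.  Calculated features cover
#' ventilatory-equivalent maxima, full-test regression slopes (VCO2 on VE, VO2
#' on VE), per-minute VO2/VE summaries and within-minute VO2-vs-time slopes for
#' incremental minutes 1-4 (half-open windows of 60 s from the incremental
#' start, warm-up excluded), intensity composites (max slope x max speed and
#' relatives), and quantities anchored at the ventilatory anaerobic threshold
#' detected by [detect_vat_vslope()].
#'
#' Provisional formulas (names whose exact published definition lives only in
#' supplementary material): `vo2_1_at_vat`/`vco2_at_vat` are the at-VAT values
#' in ml/min, `vo2_2_at_vat`/`vco2_1_at_vat` the same values relative to the
#' channel maximum, `vco2_2_at_vat` per body mass, `vslope` the single-segment
#' VCO2-vs-VO2 slope, `predicted_vo2` the below-VAT VO2-vs-time trend
#' extrapolated to the end of the test, and `pred_vo2_vat_ratio` that trend
#' evaluated at the VAT time divided by the observed VO2 at the VAT.
#'
#' Areas A and B are the trapezoidal areas under VO2 as a function of VCO2
#' (both in l/min), split at the VAT breakpoint; they sum to the total area.
#'
#' If the VAT is unreliable all VAT-anchored features are `NA`, and such
#' subjects are excluded by [extract_feature_matrix()].
#'
#' @param recording A `cpet_recording`.
#' @param registry Feature registry; the return vector follows its order.
#' @param window Rolling-mean window in breaths (default 10).
#' @param vat Optional precomputed [detect_vat_vslope()] result.
#' @return Named numeric vector of length 51 (registry order), with attributes
#'   `vat_reliable` and `window`.
#' @export
#' @examples
#' rec <- simulate_cpet(subject_profile(), seed = 3)
#' f <- extract_features(rec)
#' f[c("max_ve", "max_vo2", "rel_time_vat")]
extract_features <- function(recording, registry = feature_registry(),
                             window = 10L, vat = NULL) {
  stopifnot(inherits(recording, "cpet_recording"))
  b <- recording$breaths
  meta <- recording$meta
  mass <- meta$mass_kg %||% NA_real_
  t0 <- meta$incremental_start_s %||% 0
  out <- stats::setNames(rep(NA_real_, nrow(registry)), registry$name)

  ## direct ------------------------------------------------------------------
  out["max_time"] <- max(b$t_s)
  out["max_ve"]   <- smoothed_max(b$ve_l_min, window)
  out["max_vo2"]  <- smoothed_max(b$vo2_ml_min, window)
  out["max_vco2"] <- smoothed_max(b$vco2_ml_min, window)
  out["max_vo2_kg"] <- out["max_vo2"] / mass
  if ("rf_per_min" %in% names(b)) {
    out["max_rf"] <- smoothed_max(b$rf_per_min, window)
    out["max_vt"] <- if ("vt_l" %in% names(b)) smoothed_max(b$vt_l, window) else
      smoothed_max(b$ve_l_min / b$rf_per_min, window)
  }
  rr <- c(NA_real_, 60 / diff(b$t_s))
  out["max_rr"] <- smoothed_max(rr[-1], window)
  if ("speed_kmh" %in% names(b)) out["max_speed"] <- max(b$speed_kmh)
  if ("grade_pct" %in% names(b)) out["max_slope"] <- max(b$grade_pct)
  if ("hr_bpm" %in% names(b)) out["max_hr"] <- smoothed_max(b$hr_bpm, window)
  rer <- b$vco2_ml_min / b$vo2_ml_min
  out["max_rer"] <- smoothed_max(rer, window)

  ## calculated, full test ----------------------------------------------------
  out["max_ve_vo2"]  <- smoothed_max(b$ve_l_min / (b$vo2_ml_min / 1000), window)
  out["max_ve_vco2"] <- smoothed_max(b$ve_l_min / (b$vco2_ml_min / 1000), window)
  out["slope_vco2_ve"] <- ols_slope(b$ve_l_min, b$vco2_ml_min)
  out["slope_vo2_ve"]  <- ols_slope(b$ve_l_min, b$vo2_ml_min)
  out["max_slope_x_speed"] <- out["max_slope"] * out["max_speed"]
  out["max_slope_x_speed_x_time"] <- out["max_slope_x_speed"] * out["max_time"]
  if (is.finite(out["max_slope_x_speed"]) && out["max_slope_x_speed"] > 0) {
    out["vemax_over_slope_speed"] <- out["max_ve"] / out["max_slope_x_speed"]
    out["vo2max_over_slope_speed"] <- out["max_vo2"] / out["max_slope_x_speed"]
  }

  ## per-minute (incremental phase, half-open 60-s windows) -------------------
  tt <- b$t_s - t0
  for (k in 1:4) {
    sel <- tt >= 60 * (k - 1) & tt < 60 * k
    if (sum(sel) >= 3) {
      out[sprintf("vo2_min%d", k)] <- mean(b$vo2_ml_min[sel])
      out[sprintf("slope_vo2_min%d", k)] <-
        ols_slope(tt[sel] / 60, b$vo2_ml_min[sel])
      if (k == 1) out["ve_min1"] <- mean(b$ve_l_min[sel])
    }
  }

  ## VAT-anchored -------------------------------------------------------------
  vat <- vat %||% tryCatch(detect_vat_vslope(recording, window = window),
                           error = function(e) NULL)
  if (!is.null(vat) && isTRUE(vat$reliable)) {
    out["time_at_vat"] <- vat$time_at_vat
    out["time_to_vat"] <- vat$time_at_vat - t0
    out["time_vat_to_end"] <- out["max_time"] - vat$time_at_vat
    out["rel_time_vat"] <- vat$time_at_vat / out["max_time"]
    out["ratio_vat_vo2_max_time"] <- vat$vo2_at_vat / out["max_time"]
    imax_rer <- which.max(roll_mean(rer, window))
    vo2_at_max_rer <- mean(b$vo2_ml_min[max(1, imax_rer - window %/% 2):
                                          min(nrow(b), imax_rer + window %/% 2)])
    out["ratio_vat_rer_vo2"] <- vat$vo2_at_vat / vo2_at_max_rer
    out["slope_a"] <- vat$slope_below
    out["slope_b"] <- vat$slope_above
    out["ve_at_vat"] <- vat$ve_at_vat
    out["vco2_at_vat"] <- vat$vco2_at_vat
    out["vco2_1_at_vat"] <- vat$vco2_at_vat / out["max_vco2"]
    out["vco2_2_at_vat"] <- vat$vco2_at_vat / mass
    out["vo2_1_at_vat"] <- vat$vo2_at_vat
    out["vo2_2_at_vat"] <- vat$vo2_at_vat / out["max_vo2"]
    out["vo2_kg_at_vat"] <- vat$vo2_at_vat / mass
    out["rf_at_vat"] <- vat$rf_at_vat
    out["rr_at_vat"] <- vat$rr_at_vat
    out["vslope"] <- ols_slope(b$vo2_ml_min, b$vco2_ml_min)

    # areas of VO2 as a function of VCO2, split at the VAT breakpoint (l/min)
    inc <- b$t_s >= t0
    ordc <- order(b$vco2_ml_min[inc])
    xs <- (b$vco2_ml_min[inc][ordc]) / 1000
    ys <- (b$vo2_ml_min[inc][ordc]) / 1000
    split_at <- findInterval(vat$vco2_at_vat / 1000, xs)
    split_at <- min(max(split_at, 1L), length(xs))
    out["area_a"] <- if (split_at >= 2) trapz(xs[1:split_at], ys[1:split_at]) else 0
    out["area_b"] <- if (split_at <= length(xs) - 1)
      trapz(xs[split_at:length(xs)], ys[split_at:length(xs)]) else 0

    # below-VAT VO2-vs-time trend and its extrapolations
    below <- b$t_s >= t0 & b$t_s <= vat$time_at_vat
    if (sum(below) >= 5) {
      int_slope <- c(mean(b$vo2_ml_min[below]) -
                       ols_slope(b$t_s[below], b$vo2_ml_min[below]) * mean(b$t_s[below]),
                     ols_slope(b$t_s[below], b$vo2_ml_min[below]))
      out["predicted_vo2"] <- int_slope[1] + int_slope[2] * out["max_time"]
      out["pred_vo2_vat_ratio"] <-
        (int_slope[1] + int_slope[2] * vat$time_at_vat) / vat$vo2_at_vat
    }
  }

  attr(out, "vat_reliable") <- !is.null(vat) && isTRUE(vat$reliable)
  attr(out, "window") <- window
  out
}

#' Build the subjects x features matrix for a set of recordings
#'
#' Subjects whose feature vector contains missing values (typically because
#' the V-slope VAT was unreliable) are dropped with a message; their ids are
#' recorded in the `dropped` attribute.
#'
#' @param recordings Named list of `cpet_recording` objects.
#' @param registry Feature registry.
#' @param window Rolling-mean window in breaths.
#' @return Numeric matrix (rows = subjects, columns = 51 registry features)
#'   with attribute `dropped`.
#' @export
extract_feature_matrix <- function(recordings, registry = feature_registry(),
                                   window = 10L) {
  vecs <- lapply(recordings, extract_features, registry = registry, window = window)
  m <- do.call(rbind, vecs)
  rownames(m) <- names(recordings) %||%
    vapply(recordings, function(r) r$meta$id %||% "", "")
  ok <- stats::complete.cases(m)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " subject(s) with incomplete features ",
            "(unreliable VAT): ", paste(rownames(m)[!ok], collapse = ", "))
  }
  out <- m[ok, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[!ok]
  out
}

#' Standardize a feature matrix to column mean 0 and SD 1
#'
#' Sample SDs use the n-1 denominator.  Returns the scaler so the transform
#' can be inverted exactly and applied to new rows.
#'
#' @param matrix Numeric matrix (subjects x features).
#' @return List with `values` (standardized matrix) and `scaler` (list with
#'   `mean` and `sd`, named by feature).
#' @export
#' @examples
#' standardize(cbind(f = c(1, 2, 3)))$values
standardize <- function(matrix) {
  matrix <- as.matrix(matrix)
  mu <- colMeans(matrix)
  sd <- apply(matrix, 2, stats::sd)
  zero <- which(!(sd > 0))
  if (length(zero)) {
    stop("zero-variance column(s): ", paste(colnames(matrix)[zero], collapse = ", "))
  }
  z <- sweep(sweep(matrix, 2, mu, "-"), 2, sd, "/")
  list(values = z, scaler = list(mean = mu, sd = sd))
}

#' Apply a fitted scaler to new rows
#' @param matrix Numeric matrix or named numeric vector.
#' @param scaler Scaler from [standardize()].
#' @return Standardized matrix with the scaler's columns.
#' @export
apply_scaler <- function(matrix, scaler) {
  if (is.null(dim(matrix))) matrix <- t(as.matrix(matrix))
  matrix <- matrix[, names(scaler$mean), drop = FALSE]
  sweep(sweep(matrix, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Invert a standardization
#' @param z Standardized matrix.
#' @param scaler Scaler from [standardize()].
#' @return Matrix on the original scale.
#' @export
invert_scaler <- function(z, scaler) {
  if (is.null(dim(z))) z <- t(as.matrix(z))
  sweep(sweep(z[, names(scaler$mean), drop = FALSE], 2, scaler$sd, "*"),
        2, scaler$mean, "+")
}
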