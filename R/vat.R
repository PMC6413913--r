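# V-slope detection of the ventilatory anaerobic threshold (VAT): exhaustive
# two-segment least-squares breakpoint search on the VCO2-vs-VO2 relation.

# Per-breakpoint SSE of two independent least-squares lines, computed for every
# admissible breakpoint at once from prefix sums.  Returns list of vectors.
two_segment_profile <- function(x, y, min_points = 5L) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  seg_stats <- function(i, j) {
    # inclusive index ranges; i, j vectors of equal length
    m  <- j - i + 1
    sx <- cx[j] - ifelse(i > 1, cx[i - 1], 0)
    sy <- cy[j] - ifelse(i > 1, cy[i - 1], 0)
    sxx <- cxx[j] - ifelse(i > 1, cxx[i - 1], 0)
    syy <- cyy[j] - ifelse(i > 1, cyy[i - 1], 0)
    sxy <- cxy[j] - ifelse(i > 1, cxy[i - 1], 0)
    vxx <- sxx - sx^2 / m
    vyy <- syy - sy^2 / m
    vxy <- sxy - sx * sy / m
    slope <- ifelse(vxx > .Machine$double.eps * pmax(sxx, 1), vxy / vxx, 0)
    sse <- vyy - slope * vxy
    list(slope = slope, sse = pmax(sse, 0))
  }
  b <- seq.int(min_points, n - min_points)        # last index of lower segment
  lo <- seg_stats(rep.int(1L, length(b)), b)
  hi <- seg_stats(b + 1L, rep.int(n, length(b)))
  one <- seg_stats(1L, n)
  list(breaks = b, sse = lo$sse + hi$sse,
       slope_below = lo$slope, slope_above = hi$slope,
       sse_one = one$sse, slope_one = one$slope)
}

#' Detect the ventilatory anaerobic threshold by the V-slope method
#'
#' Fits two independent least-squares lines to the VCO2-vs-VO2 relation of a
#' recording (breaths ordered by VO2), searching exhaustively over every
#' admissible breakpoint with at least `min_points` breaths per segment, and
#' returns the breakpoint minimizing the total sum of squared errors.  The fit
#' is declared unreliable when the two-segment SSE improves on the
#' single-segment SSE by less than `improvement` (relative), or when the
#' above-VAT slope does not exceed the below-VAT slope -- both indicate the
#' absence of the disproportionate VCO2 rise the V-slope method looks for.
#'
#' @param recording A `cpet_recording` (see [simulate_cpet()]) or a data.frame
#'   with at least columns `vo2_ml_min` and `vco2_ml_min`.  When recording
#'   metadata marks an incremental start time, warm-up breaths are excluded.
#' @param min_points Minimum breaths per segment (default 5).
#' @param improvement Minimum relative SSE improvement of the two-segment fit
#'   over the one-segment fit for the VAT to count as reliable (default 0.05).
#' @param window Breath window for reporting channel values at the VAT
#'   (centered rolling mean; default 10 breaths).
#' @return An object of class `vat_point`: list with `breath_index` (index into
#'   the recording's breath table), `vo2_at_vat`, `vco2_at_vat`, `time_at_vat`,
#'   `ve_at_vat`, `rf_at_vat`, `rr_at_vat`, `slope_below`, `slope_above`,
#'   `sse`, `sse_one_segment` and `reliable`.
#' @export
#' @examples
#' prof <- subject_profile(id = "s1", sex = "male")
#' rec <- simulate_cpet(prof, seed = 1)
#' detect_vat_vslope(rec)
detect_vat_vslope <- function(recording, min_points = 5L, improvement = 0.05,
                              window = 10L) {
  breaths <- if (inherits(recording, "cpet_recording")) recording$breaths else recording
  if (!all(c("vo2_ml_min", "vco2_ml_min") %in% names(breaths))) {
    stop("recording must contain columns vo2_ml_min and vco2_ml_min")
  }
  start_s <- if (inherits(recording, "cpet_recording")) {
    recording$meta$incremental_start_s %||% -Inf
  } else -Inf
  keep <- if ("t_s" %in% names(breaths)) breaths$t_s >= start_s else rep(TRUE, nrow(breaths))
  idx_all <- which(keep)
  vo2 <- breaths$vo2_ml_min[idx_all]
  vco2 <- breaths$vco2_ml_min[idx_all]
  n <- length(vo2)
  if (n < max(20L, 2L * min_points)) {
    stop("insufficient data: need at least ", max(20L, 2L * min_points),
         " breaths for V-slope detection, got ", n)
  }
  if (diff(range(vo2)) <= 0) stop("degenerate VO2 span")
  ord <- order(vo2)
  prof <- two_segment_profile(vo2[ord], vco2[ord], min_points = min_points)
  best <- which.min(prof$sse)
  b <- prof$breaks[best]
  # a one-segment fit that is already essentially exact leaves nothing for a
  # breakpoint to explain
  sse_floor <- 1e-9 * sum(vco2^2)
  rel_gain <- if (prof$sse_one <= sse_floor) 0 else 1 - prof$sse[best] / prof$sse_one
  reliable <- rel_gain >= improvement &&
    prof$slope_above[best] > prof$slope_below[best]
  breath_sorted <- idx_all[ord[b]]

  at <- function(col) {
    if (!col %in% names(breaths)) return(NA_real_)
    # local mean around the breakpoint breath, in time order
    pos <- ord[b]
    w <- max(1L, window %/% 2L)
    sel <- idx_all[max(1L, pos - w):min(n, pos + w)]
    mean(breaths[[col]][sel])
  }
  rr <- if ("t_s" %in% names(breaths) && nrow(breaths) > 1) {
    tt <- breaths$t_s
    r <- c(NA_real_, 60 / diff(tt))
    pos <- ord[b]; w <- max(1L, window %/% 2L)
    sel <- idx_all[max(1L, pos - w):min(n, pos + w)]
    mean(r[sel], na.rm = TRUE)
  } else NA_real_

  structure(list(
    breath_index = breath_sorted,
    vo2_at_vat = vo2[ord[b]],
    vco2_at_vat = vco2[ord[b]],
    time_at_vat = at("t_s"),
    ve_at_vat = at("ve_l_min"),
    rf_at_vat = at("rf_per_min"),
    rr_at_vat = rr,
    slope_below = prof$slope_below[best],
    slope_above = prof$slope_above[best],
    sse = prof$sse[best],
    sse_one_segment = prof$sse_one,
    relative_improvement = rel_gain,
    reliable = reliable
  ), class = "vat_point")
}

#' @export
print.vat_point <- function(x, ...) {
  cat("V-slope VAT:", if (x$reliable) "reliable" else "UNRELIABLE", "\n")
  cat(sprintf("  VO2 at VAT: %.0f ml/min (breath %d, t = %.0f s)\n",
              x$vo2_at_vat, x$breath_index, x$time_at_vat))
  cat(sprintf("  slopes below/above: %.3f / %.3f, SSE improvement %.1f%%\n",
              x$slope_below, x$slope_above, 100 * x$relative_improvement))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
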