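# Synthetic cohort generator: breath-by-breath incremental treadmill CPET
# recordings paired with Wingate outcomes carrying a planted linear signal.

#' Subject profile for simulation
#'
#' @param id Subject identifier.
#' @param sex `"female"` or `"male"`.
#' @param age Years.
#' @param mass Body mass in kg (must be positive).
#' @param height Height in cm.
#' @param vo2max_true True maximal oxygen uptake in ml/min.
#' @param vat_fraction Ventilatory anaerobic threshold as a fraction of
#'   VO2max, in (0, 1).
#' @param ve_max_true True maximal minute ventilation in l/min.
#' @param hr_max Maximal heart rate in beats/min; the simulated test ends when
#'   modeled heart rate reaches it.
#' @param rer_max Modeled respiratory exchange ratio at exhaustion.
#' @param vslope_below Below-VAT slope of the modeled VCO2-vs-VO2 relation.
#' @param ramp_duration_s Seconds the subject takes to ramp from baseline to
#'   VO2max during the incremental phase.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(id = "s1", sex = c("male", "female"), age = 28,
                            mass = 75, height = 176, vo2max_true = 4000,
                            vat_fraction = 0.65, ve_max_true = 140,
                            hr_max = 186, rer_max = 1.12, vslope_below = 0.85,
                            ramp_duration_s = 600) {
  sex <- match.arg(sex)
  stopifnot(mass > 0, vo2max_true > 0, ve_max_true > 0, hr_max > 0,
            vat_fraction > 0, vat_fraction < 1, ramp_duration_s > 60)
  structure(list(id = id, sex = sex, age = age, mass = mass, height = height,
                 vo2max_true = vo2max_true, vat_fraction = vat_fraction,
                 ve_max_true = ve_max_true, hr_max = hr_max,
                 rer_max = rer_max, vslope_below = vslope_below,
                 ramp_duration_s = ramp_duration_s),
            class = "subject_profile")
}

#' Incremental treadmill protocol specification
#'
#' The default protocol raises treadmill speed by 1 km/h each minute and, once
#' the modeled respiratory quotient reaches `rq_trigger`, raises the grade by
#' `grade_increment_pct` at the trigger and at each subsequent minute boundary
#' (`grade_mode = "per_minute"`); `grade_mode = "once"` applies a single step.
#' The warm-up speed and starting speed are configurable defaults, not values
#' prescribed by any study protocol.
#'
#' @param warmup_s Warm-up duration in seconds (constant low speed).
#' @param speed_start Warm-up/starting speed in km/h.
#' @param speed_increment Speed increase per minute in km/h (> 0).
#' @param grade_increment_pct Grade increase in percent (>= 0).
#' @param rq_trigger RER value triggering the grade increase (default 1.0).
#' @param grade_mode `"per_minute"` or `"once"`.
#' @param breath_interval_s Mean seconds between breaths.
#' @param breath_jitter_s Half-width of the uniform jitter on breath intervals.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(warmup_s = 120, speed_start = 5, speed_increment = 1,
                          grade_increment_pct = 2, rq_trigger = 1.0,
                          grade_mode = c("per_minute", "once"),
                          breath_interval_s = 2, breath_jitter_s = 0.5) {
  grade_mode <- match.arg(grade_mode)
  if (!is.numeric(speed_increment) || speed_increment <= 0) {
    stop("invalid protocol: speed_increment must be > 0")
  }
  if (!is.numeric(grade_increment_pct) || grade_increment_pct < 0) {
    stop("invalid protocol: grade_increment_pct must be >= 0")
  }
  stopifnot(warmup_s >= 0, breath_interval_s > 0,
            breath_jitter_s >= 0, breath_jitter_s < breath_interval_s)
  structure(list(warmup_s = warmup_s, speed_start = speed_start,
                 speed_increment = speed_increment,
                 grade_increment_pct = grade_increment_pct,
                 rq_trigger = rq_trigger, grade_mode = grade_mode,
                 breath_interval_s = breath_interval_s,
                 breath_jitter_s = breath_jitter_s),
            class = "protocol_spec")
}

#' Breath-level noise specification
#'
#' Fractional (multiplicative Gaussian) noise per channel.  Setting all to 0
#' yields noiseless model curves.
#' @param vo2,vco2,ve,rf,hr Fractional standard deviations.
#' @return Named list.
#' @export
cpet_noise <- function(vo2 = 0.02, vco2 = 0.02, ve = 0.03, rf = 0.05,
                       hr = 0.005) {
  list(vo2 = vo2, vco2 = vco2, ve = ve, rf = rf, hr = hr)
}

#' Simulate one breath-by-breath incremental CPET recording
#'
#' Minimal physiological model: VO2 rises linearly from a walking baseline to
#' `vo2max_true` over the subject's ramp duration; VCO2 follows a two-segment
#' (V-slope) relation with breakpoint at `vat_fraction * vo2max_true`; VE is
#' proportional to VCO2 and therefore steepens above the VAT; heart rate is
#' linear in %VO2max and the recording ends when it reaches `hr_max`.  The
#' modeled RER crosses the protocol's `rq_trigger` exactly once, at which point
#' the treadmill grade starts increasing.
#'
#' @param profile A [subject_profile()].
#' @param protocol A [protocol_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param noise A [cpet_noise()] list.
#' @return An object of class `cpet_recording`: list with `breaths` (data.frame
#'   with columns `t_s`, `vo2_ml_min`, `vco2_ml_min`, `ve_l_min`, `rf_per_min`,
#'   `vt_l`, `hr_bpm`, `speed_kmh`, `grade_pct`) and `meta` (subject fields,
#'   `incremental_start_s`, per-minute `schedule`, and generative truth).
#' @export
#' @examples
#' rec <- simulate_cpet(subject_profile(), seed = 42)
#' head(rec$breaths)
simulate_cpet <- function(profile, protocol = protocol_spec(), seed = NULL,
                          noise = cpet_noise()) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!inherits(protocol, "protocol_spec")) stop("invalid protocol")
  if (protocol$speed_increment <= 0) stop("invalid protocol: speed_increment must be > 0")
  if (protocol$grade_increment_pct < 0) stop("invalid protocol: grade_increment_pct must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  w <- protocol$warmup_s
  ramp <- profile$ramp_duration_s
  t_end <- w + ramp
  vo2max <- profile$vo2max_true
  base_frac <- 0.25
  vat_vo2 <- profile$vat_fraction * vo2max
  s_lo <- profile$vslope_below
  # above-VAT slope chosen so that RER at exhaustion equals rer_max
  s_hi <- (profile$rer_max - s_lo * profile$vat_fraction) /
    (1 - profile$vat_fraction)

  # breath times
  n_guess <- ceiling(t_end / (protocol$breath_interval_s - protocol$breath_jitter_s)) + 2L
  ints <- protocol$breath_interval_s +
    stats::runif(n_guess, -protocol$breath_jitter_s, protocol$breath_jitter_s)
  t <- cumsum(ints)
  t <- t[t <= t_end]

  frac <- ifelse(t <= w, base_frac,
                 base_frac + (1 - base_frac) * pmin(1, (t - w) / ramp))
  vo2_true <- frac * vo2max
  vco2_of <- function(v) ifelse(v <= vat_vo2, s_lo * v,
                                s_lo * vat_vo2 + s_hi * (v - vat_vo2))
  vco2_true <- vco2_of(vo2_true)
  vco2_max_true <- vco2_of(vo2max)
  ve_true <- profile$ve_max_true * vco2_true / vco2_max_true
  rf_true <- 16 + 34 * frac
  hr_rest <- 65
  hr_true <- hr_rest + (profile$hr_max - hr_rest) * frac

  # grade trigger: modeled RER crosses rq_trigger once, above the VAT
  t_trigger <- if (s_hi > protocol$rq_trigger && protocol$rq_trigger > s_lo) {
    vo2_r <- vat_vo2 * (s_hi - s_lo) / (s_hi - protocol$rq_trigger)
    if (vo2_r <= vo2max) w + ramp * (vo2_r / vo2max - base_frac) / (1 - base_frac) else Inf
  } else Inf

  minute <- ifelse(t <= w, 0L, floor((t - w) / 60) + 1L)
  speed <- ifelse(t <= w, protocol$speed_start,
                  protocol$speed_start + minute * protocol$speed_increment)
  grade <- numeric(length(t))
  if (is.finite(t_trigger)) {
    m0 <- floor((t_trigger - w) / 60)
    after <- t >= t_trigger
    if (protocol$grade_mode == "once") {
      grade[after] <- protocol$grade_increment_pct
    } else {
      grade[after] <- protocol$grade_increment_pct *
        (floor((t[after] - w) / 60) - m0 + 1)
    }
  }

  jit <- function(x, sd) if (sd > 0) x * (1 + stats::rnorm(length(x), 0, sd)) else x
  vo2 <- jit(vo2_true, noise$vo2)
  vco2 <- jit(vco2_true, noise$vco2)
  ve <- jit(ve_true, noise$ve)
  rf <- jit(rf_true, noise$rf)
  hr <- jit(hr_true, noise$hr)

  breaths <- data.frame(
    t_s = t, vo2_ml_min = vo2, vco2_ml_min = vco2, ve_l_min = ve,
    rf_per_min = rf, vt_l = ve / rf, hr_bpm = hr,
    speed_kmh = speed, grade_pct = grade
  )
  sched_min <- seq_len(max(minute))
  schedule <- data.frame(
    minute = sched_min,
    speed_kmh = protocol$speed_start + sched_min * protocol$speed_increment,
    grade_pct = vapply(sched_min, function(m) {
      tm <- w + (m - 1) * 60
      if (!is.finite(t_trigger) || tm + 60 <= t_trigger) 0 else {
        if (protocol$grade_mode == "once") protocol$grade_increment_pct
        else protocol$grade_increment_pct * (m - floor((t_trigger - w) / 60))
      }
    }, numeric(1))
  )
  cpet_recording(breaths, meta = list(
    id = profile$id, sex = profile$sex, age = profile$age,
    mass_kg = profile$mass, height_cm = profile$height,
    warmup_s = w, incremental_start_s = w, schedule = schedule,
    protocol = unclass(protocol),
    truth = list(vo2max = vo2max, vat_vo2 = vat_vo2, t_trigger = t_trigger,
                 ramp_duration_s = ramp, slope_below = s_lo, slope_above = s_hi)
  ))
}

#' Construct (and validate) a CPET recording object
#'
#' @param breaths Breath-by-breath data.frame with at minimum `t_s`,
#'   `vo2_ml_min`, `vco2_ml_min`, `ve_l_min`.
#' @param meta List of metadata (subject id, mass_kg, incremental_start_s, ...).
#' @return `cpet_recording` object.
#' @export
cpet_recording <- function(breaths, meta = list()) {
  required <- c("t_s", "vo2_ml_min", "vco2_ml_min", "ve_l_min")
  missing <- setdiff(required, names(breaths))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- which(diff(breaths$t_s) <= 0)
  if (length(bad)) stop("non-monotone breath times at row ", bad[1] + 1L)
  structure(list(breaths = breaths, meta = meta), class = "cpet_recording")
}

#' @export
print.cpet_recording <- function(x, ...) {
  cat(sprintf("CPET recording '%s': %d breaths over %.0f s\n",
              x$meta$id %||% "?", nrow(x$breaths), max(x$breaths$t_s)))
  invisible(x)
}

#' Simulate a 30-s Wingate anaerobic test
#'
#' Builds a 30-s power curve (linear rise to peak over `peak_time_s`, then
#' linear decay to `end_w`), samples it on a fine grid, and summarizes it the
#' way the ergometer does: peak power is the curve maximum, mean power the
#' time average over the 30 s (trapezoidal), and the fatigue index the percent
#' drop from maximal to minimal power.  The braking resistance is fixed at
#' 0.075 of body mass.
#'
#' @param profile Optional [subject_profile()] used for default peak power and
#'   the absolute resistance load.
#' @param shape List of curve parameters: `peak_w`, `end_w`, `peak_time_s`
#'   (0 gives a monotone decay from the peak), `start_frac` (initial power as a
#'   fraction of peak when `peak_time_s > 0`), `noise_sd` (additive W).
#' @param seed Integer seed for curve noise.
#' @param dt Sampling interval of the power curve in seconds.
#' @return Object of class `wingate_result` with fields `pp`, `mp`, `fatigue`,
#'   `power_curve` (data.frame `t`, `power`), `resistance` (0.075) and
#'   `load_kg` when mass is known.
#' @export
#' @examples
#' simulate_wingate(shape = list(peak_w = 800, end_w = 400, peak_time_s = 0))
simulate_wingate <- function(profile = NULL, shape = list(), seed = NULL,
                             dt = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  mass <- if (!is.null(profile)) profile$mass else NA_real_
  default_peak <- if (!is.null(profile)) {
    mass * if (profile$sex == "male") 10.1 else 7.4
  } else 750
  peak <- shape$peak_w %||% default_peak
  end <- shape$end_w %||% (0.5 * peak)
  tp <- shape$peak_time_s %||% 2
  start_frac <- shape$start_frac %||% 0.85
  noise_sd <- shape$noise_sd %||% 0
  if (!is.numeric(peak) || peak <= 0 || end <= 0) {
    stop("invalid shape: power curve must be positive")
  }
  t <- seq(0, 30, by = dt)
  power <- if (tp > 0) {
    ifelse(t <= tp, start_frac * peak + (1 - start_frac) * peak * t / tp,
           peak + (end - peak) * (t - tp) / (30 - tp))
  } else {
    peak + (end - peak) * t / 30
  }
  if (noise_sd > 0) power <- pmax(1, power + stats::rnorm(length(t), 0, noise_sd))
  pp <- max(power)
  mp <- trapz(t, power) / 30
  fatigue <- 100 * (max(power) - min(power)) / max(power)
  structure(list(pp = pp, mp = mp, fatigue = fatigue,
                 power_curve = data.frame(t = t, power = power),
                 resistance = 0.075,
                 load_kg = if (is.na(mass)) NA_real_ else 0.075 * mass),
            class = "wingate_result")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' @export
print.wingate_result <- function(x, ...) {
  cat(sprintf("Wingate: PP = %.1f W, MP = %.1f W, fatigue = %.1f%%\n",
              x$pp, x$mp, x$fatigue))
  invisible(x)
}

#' Generative specification for planted cohort outcomes
#'
#' Defines the linear model by which one anaerobic outcome is planted on
#' standardized aerobic features:
#' `outcome = intercept + sum(coefficients * z(feature)) + Normal(0, noise_sd)`.
#'
#' @param signal_features Canonical registry names of the signal features.
#' @param coefficients Numeric weights, one per signal feature (outcome units
#'   per standardized unit).
#' @param intercept Outcome units (W, or % for fatigue).
#' @param noise_sd Residual standard deviation (>= 0).  The special value
#'   `"r2"` together with `target_r2` calibrates the noise so the planted
#'   linear model explains approximately `target_r2` of the outcome variance.
#' @param outcome One of `"pp_w"`, `"mp_w"`, `"fatigue_pct"`.
#' @param target_r2 Population R-squared used when `noise_sd = "r2"`.
#' @return List of class `generative_spec`.
#' @export
generative_spec <- function(signal_features = c("max_ve", "max_vo2", "max_slope_x_speed"),
                            coefficients = c(120, 60, 40), intercept = 600,
                            noise_sd = 40, outcome = c("pp_w", "mp_w", "fatigue_pct"),
                            target_r2 = NULL) {
  outcome <- match.arg(outcome)
  reg <- feature_registry()
  bad <- setdiff(signal_features, reg$name)
  if (length(bad)) stop("signal features not in registry: ", paste(bad, collapse = ", "))
  stopifnot(length(coefficients) == length(signal_features))
  if (is.numeric(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (identical(noise_sd, "r2") && is.null(target_r2)) {
    stop("target_r2 required when noise_sd = \"r2\"")
  }
  structure(list(signal_features = signal_features,
                 coefficients = stats::setNames(coefficients, signal_features),
                 intercept = intercept, noise_sd = noise_sd,
                 outcome = outcome, target_r2 = target_r2),
            class = "generative_spec")
}

# Table-1-style anthropometric / aerobic parameter distributions by sex.
# Truncated normals (+-3 SD, physiologic floors).
cohort_defaults <- function() {
  list(
    female = list(age = c(25, 4), height = c(164.3, 6.4), mass = c(60.7, 8.7),
                  vo2max = c(2585.9, 382.7), ve_max = c(87.2, 14.5),
                  hr_max = c(183, 7.8)),
    male = list(age = c(28, 6), height = c(176.6, 6.8), mass = c(75.8, 10.2),
                vo2max = c(4169.2, 605.8), ve_max = c(146.5, 20.6),
                hr_max = c(186, 7.3)),
    vat_fraction = c(0.65, 0.05),
    rer_max = c(1.12, 0.04),
    vslope_below = c(0.85, 0.03),
    ramp_duration_s = c(600, 60),
    floors = c(age = 18, height = 140, mass = 35, vo2max = 800, ve_max = 30,
               hr_max = 120)
  )
}

rtnorm <- function(n, mean, sd, lower = mean - 3 * sd, upper = mean + 3 * sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Draw subject profiles from the cohort defaults
#'
#' @param n Number of subjects.
#' @param sex Character vector of length `n` (recycled), or `NULL` to draw the
#'   default mix (36:52 female:male).
#' @return List of [subject_profile()] objects. Uses the current RNG state.
#' @export
sample_profiles <- function(n, sex = NULL) {
  d <- cohort_defaults()
  if (is.null(sex)) {
    sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(36, 52))
  }
  sex <- rep_len(sex, n)
  draw <- function(par, sx) {
    p <- d[[sx]][[par]]
    fl <- d$floors[[par]]
    rtnorm(1, p[1], p[2], lower = max(p[1] - 3 * p[2], fl))
  }
  lapply(seq_len(n), function(i) {
    sx <- sex[i]
    subject_profile(
      id = sprintf("s%03d", i), sex = sx,
      age = draw("age", sx), mass = draw("mass", sx),
      height = draw("height", sx), vo2max_true = draw("vo2max", sx),
      vat_fraction = rtnorm(1, d$vat_fraction[1], d$vat_fraction[2],
                            lower = 0.45, upper = 0.85),
      ve_max_true = draw("ve_max", sx), hr_max = draw("hr_max", sx),
      rer_max = rtnorm(1, d$rer_max[1], d$rer_max[2], lower = 1.02),
      vslope_below = rtnorm(1, d$vslope_below[1], d$vslope_below[2],
                            lower = 0.7, upper = 0.98),
      ramp_duration_s = rtnorm(1, d$ramp_duration_s[1], d$ramp_duration_s[2],
                               lower = 360)
    )
  })
}

#' Simulate a paired CPET + Wingate cohort with planted linear structure
#'
#' Draws `n` subject profiles from the cohort defaults, simulates one CPET
#' recording each, extracts and standardizes the 51 aerobic features, and
#' plants the anaerobic outcome named in `gen` as a linear function of the
#' standardized signal features plus Gaussian noise.  The remaining outcomes
#' are filled with simple physiologic correlates so the manifest is complete.
#' A master seed deterministically spawns per-subject breath-noise streams.
#'
#' @param n Cohort size (>= 10).
#' @param gen A [generative_spec()].
#' @param protocol A [protocol_spec()].
#' @param seed Master integer seed.
#' @param sex_counts Optional named vector `c(female = ..., male = ...)`
#'   summing to `n`.
#' @param noise A [cpet_noise()] list for breath-level noise.
#' @param window Smoothing window (breaths) passed to feature extraction.
#' @return Object of class `aeropower_cohort`: list with `recordings` (list of
#'   `cpet_recording`), `wingate` (list of `wingate_result`), `manifest`
#'   (data.frame: id, sex, age, mass_kg, height_cm, pp_w, mp_w, fatigue_pct),
#'   `features` (raw n x 51 matrix), `features_std`, `scaler`, and `truth`
#'   (generative spec, true coefficients, signal feature names, noise_sd used,
#'   ids dropped for unreliable VAT).
#' @export
#' @examples
#' coh <- simulate_cohort(12, seed = 7)
#' dim(coh$features)
simulate_cohort <- function(n, gen = generative_spec(), protocol = protocol_spec(),
                            seed = 1, sex_counts = NULL, noise = cpet_noise(),
                            window = 10L) {
  if (n < 10) stop("too small cohort: n must be >= 10 for downstream splitting")
  stopifnot(inherits(gen, "generative_spec"))
  set.seed(seed)
  sex <- NULL
  if (!is.null(sex_counts)) {
    if (sum(sex_counts) != n) stop("sex_counts must sum to n")
    sex <- sample(rep(names(sex_counts), sex_counts))
  }
  profiles <- sample_profiles(n, sex = sex)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  recordings <- lapply(seq_len(n), function(i) {
    simulate_cpet(profiles[[i]], protocol, seed = subject_seeds[i], noise = noise)
  })
  names(recordings) <- vapply(profiles, `[[`, "", "id")

  fm <- extract_feature_matrix(recordings, window = window)
  dropped <- attr(fm, "dropped")
  keep_ids <- rownames(fm)
  profiles <- profiles[match(keep_ids, names(recordings))]
  recordings <- recordings[keep_ids]

  std <- standardize(fm)
  z <- std$values
  sig <- z[, gen$signal_features, drop = FALSE]
  signal <- as.numeric(gen$intercept + sig %*% gen$coefficients)
  noise_sd <- gen$noise_sd
  if (identical(noise_sd, "r2")) {
    # calibrate residual noise so the planted model explains ~ target_r2
    noise_sd <- stats::sd(signal) * sqrt((1 - gen$target_r2) / gen$target_r2)
  }
  set.seed(subject_seeds[1] %% 100000L + 17L)  # outcome-noise stream
  y <- signal + stats::rnorm(length(signal), 0, noise_sd)

  m <- length(y)
  pp <- mp <- fat <- NULL
  if (gen$outcome == "pp_w") {
    pp <- y
    mp <- 0.72 * pp + stats::rnorm(m, 0, 25)
    fat <- pmin(90, pmax(10, stats::rnorm(m, 50, 12)))
  } else if (gen$outcome == "mp_w") {
    mp <- y
    pp <- mp / 0.72 + stats::rnorm(m, 0, 35)
    fat <- pmin(90, pmax(10, stats::rnorm(m, 50, 12)))
  } else {
    fat <- pmin(95, pmax(5, y))
    pp <- vapply(profiles, function(p) p$mass * if (p$sex == "male") 10.1 else 7.4,
                 numeric(1)) + stats::rnorm(m, 0, 60)
    mp <- 0.72 * pp + stats::rnorm(m, 0, 25)
  }
  pp <- pmax(pp, 50); mp <- pmax(mp, 30)

  wingate <- lapply(seq_len(m), function(i) {
    wingate_from_summary(pp[i], mp[i], fat[i], mass = profiles[[i]]$mass)
  })
  names(wingate) <- keep_ids

  manifest <- data.frame(
    id = keep_ids,
    sex = vapply(profiles, `[[`, "", "sex"),
    age = vapply(profiles, `[[`, 0, "age"),
    mass_kg = vapply(profiles, `[[`, 0, "mass"),
    height_cm = vapply(profiles, `[[`, 0, "height"),
    pp_w = pp, mp_w = mp, fatigue_pct = fat,
    stringsAsFactors = FALSE
  )
  structure(list(recordings = recordings, wingate = wingate,
                 manifest = manifest, features = fm, features_std = z,
                 scaler = std$scaler,
                 truth = list(spec = gen, coefficients = gen$coefficients,
                              signal_features = gen$signal_features,
                              intercept = gen$intercept, noise_sd = noise_sd,
                              planted_outcome = y, dropped = dropped)),
            class = "aeropower_cohort")
}

# Build a 30-s power curve consistent with given (pp, mp, fatigue) summaries
# where geometrically feasible: peak at t = 0, one interior node at t = 10 s
# chosen to match the mean, linear decay to the minimum at 30 s.
wingate_from_summary <- function(pp, mp, fatigue, mass = NA_real_) {
  p_min <- pp * (1 - fatigue / 100)
  p1 <- (30 * mp - 5 * pp - 10 * p_min) / 15
  p1 <- min(max(p1, p_min), pp)
  t <- seq(0, 30, by = 0.1)
  power <- ifelse(t <= 10, pp + (p1 - pp) * t / 10,
                  p1 + (p_min - p1) * (t - 10) / 20)
  structure(list(pp = max(power), mp = trapz(t, power) / 30,
                 fatigue = 100 * (max(power) - min(power)) / max(power),
                 power_curve = data.frame(t = t, power = power),
                 resistance = 0.075,
                 load_kg = if (is.na(mass)) NA_real_ else 0.075 * mass),
            class = "wingate_result")
}

#' @export
print.aeropower_cohort <- function(x, ...) {
  cat(sprintf("aeropower cohort: %d subjects (%d female, %d male), outcome '%s'\n",
              nrow(x$manifest), sum(x$manifest$sex == "female"),
              sum(x$manifest$sex == "male"), x$truth$spec$outcome))
  if (length(x$truth$dropped)) {
    cat("  dropped (unreliable VAT):", paste(x$truth$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
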