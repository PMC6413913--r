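# Canonical registry of the 51 aerobic CPET features: 12 directly measured
# channels/maxima and 39 calculated features (ratios, slopes, per-minute
# values, ventilatory-threshold-anchored quantities).

#' Canonical aerobic feature registry
#'
#' Returns the ordered registry of the 51 aerobic features extracted from a
#' maximal incremental CPET recording: 12 `direct` features (smoothed maxima or
#' terminal values of measured channels) and 39 `calculated` features (ratios,
#' regression slopes, per-minute summaries, and quantities anchored at the
#' ventilatory anaerobic threshold, VAT).  The `stage` column tags the
#' features computable from the first four minutes of the incremental phase
#' (`early_minutes`) versus those requiring the whole test (`full_test`).
#'
#' Several registry names only appear in supplementary material of the source
#' literature and carry a provisional formula here; they are marked in the
#' `provisional` column and their definitions are documented in
#' [extract_features()].
#'
#' @return A data.frame with columns `name`, `class` (`direct`/`calculated`),
#'   `stage` (`full_test`/`early_minutes`), `provisional` (logical) and
#'   `description`, with exactly 51 rows.
#' @seealso [feature_aliases()], [extract_features()]
#' @export
#' @examples
#' reg <- feature_registry()
#' table(reg$class)
feature_registry <- function() {
  def <- function(name, class, stage, description, provisional = FALSE) {
    data.frame(name = name, class = class, stage = stage,
               provisional = provisional, description = description,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    ## ---- 12 direct features -------------------------------------------------
    def("max_time",    "direct", "full_test", "duration of the test [s]"),
    def("max_vt",      "direct", "full_test", "maximal tidal volume [l]"),
    def("max_ve",      "direct", "full_test", "maximal minute ventilation [l/min]"),
    def("max_vo2",     "direct", "full_test", "maximal oxygen uptake [ml/min]"),
    def("max_vco2",    "direct", "full_test", "maximal carbon-dioxide output [ml/min]"),
    def("max_vo2_kg",  "direct", "full_test", "maximal oxygen uptake per body mass [ml/min/kg]"),
    def("max_rr",      "direct", "full_test", "maximal respiratory rate from breath timing [breaths/min]"),
    def("max_rf",      "direct", "full_test", "maximal device-reported respiratory frequency [breaths/min]"),
    def("max_speed",   "direct", "full_test", "maximal treadmill speed [km/h]"),
    def("max_slope",   "direct", "full_test", "maximal treadmill slope (grade) [%]"),
    def("max_hr",      "direct", "full_test", "maximal heart rate [beats/min]"),
    def("max_rer",     "direct", "full_test", "maximal respiratory exchange ratio VCO2/VO2"),
    ## ---- calculated, full-test ---------------------------------------------
    def("max_ve_vo2",  "calculated", "full_test", "maximal ventilatory equivalent for O2 (VE/VO2)"),
    def("max_ve_vco2", "calculated", "full_test", "maximal ventilatory equivalent for CO2 (VE/VCO2)"),
    def("slope_vco2_ve", "calculated", "full_test", "slope of VCO2 versus VE over the full test"),
    def("slope_vo2_ve",  "calculated", "full_test", "slope of VO2 versus VE over the full test"),
    def("max_slope_x_speed", "calculated", "full_test", "max slope * max speed"),
    def("max_slope_x_speed_x_time", "calculated", "full_test", "max slope * max speed * max time"),
    def("vemax_over_slope_speed", "calculated", "full_test", "VEmax / (max slope * max speed)"),
    def("vo2max_over_slope_speed", "calculated", "full_test", "VO2max / (max slope * max speed)"),
    def("predicted_vo2", "calculated", "full_test",
        "VO2 predicted at end of test from the below-VAT VO2-vs-time trend [ml/min]", TRUE),
    ## ---- calculated, VAT-anchored ------------------------------------------
    def("time_at_vat",  "calculated", "full_test", "recording time at the VAT [s]"),
    def("time_to_vat",  "calculated", "full_test", "time from incremental start to the VAT [s]"),
    def("time_vat_to_end", "calculated", "full_test", "time from the VAT to the end of the test [s]"),
    def("rel_time_vat", "calculated", "full_test", "time at VAT / total test duration"),
    def("ratio_vat_vo2_max_time", "calculated", "full_test", "VO2 at VAT [ml/min] / test duration [s]"),
    def("ratio_vat_rer_vo2", "calculated", "full_test", "VO2 at VAT / VO2 at the point of maximal RER"),
    def("slope_a", "calculated", "full_test", "below-VAT slope of the VCO2-vs-VO2 two-segment fit"),
    def("slope_b", "calculated", "full_test", "above-VAT slope of the VCO2-vs-VO2 two-segment fit"),
    def("area_a", "calculated", "full_test", "trapezoidal area of VO2 as a function of VCO2 below the VAT [(l/min)^2]"),
    def("area_b", "calculated", "full_test", "trapezoidal area of VO2 as a function of VCO2 above the VAT [(l/min)^2]"),
    def("ve_at_vat",   "calculated", "full_test", "minute ventilation at the VAT [l/min]"),
    def("vco2_at_vat", "calculated", "full_test", "VCO2 at the VAT [ml/min]"),
    def("vco2_1_at_vat", "calculated", "full_test", "VCO2 at VAT as a fraction of max VCO2", TRUE),
    def("vco2_2_at_vat", "calculated", "full_test", "VCO2 at VAT per body mass [ml/min/kg]", TRUE),
    def("vo2_1_at_vat", "calculated", "full_test", "VO2 at the VAT [ml/min]", TRUE),
    def("vo2_2_at_vat", "calculated", "full_test", "VO2 at VAT as a fraction of max VO2", TRUE),
    def("vo2_kg_at_vat", "calculated", "full_test", "VO2 at the VAT per body mass [ml/min/kg]"),
    def("rf_at_vat", "calculated", "full_test", "respiratory frequency at the VAT [breaths/min]"),
    def("rr_at_vat", "calculated", "full_test", "respiratory rate from breath timing at the VAT [breaths/min]"),
    def("vslope", "calculated", "full_test", "overall single-segment slope of VCO2 versus VO2", TRUE),
    def("pred_vo2_vat_ratio", "calculated", "full_test",
        "below-VAT VO2 trend extrapolated to the VAT time / observed VO2 at VAT", TRUE),
    ## ---- calculated, early minutes -----------------------------------------
    def("vo2_min1", "calculated", "early_minutes", "mean VO2 during incremental minute 1 [ml/min]"),
    def("vo2_min2", "calculated", "early_minutes", "mean VO2 during incremental minute 2 [ml/min]"),
    def("vo2_min3", "calculated", "early_minutes", "mean VO2 during incremental minute 3 [ml/min]"),
    def("vo2_min4", "calculated", "early_minutes", "mean VO2 during incremental minute 4 [ml/min]"),
    def("slope_vo2_min1", "calculated", "early_minutes", "slope of VO2 vs time within minute 1 [ml/min per min]"),
    def("slope_vo2_min2", "calculated", "early_minutes", "slope of VO2 vs time within minute 2 [ml/min per min]"),
    def("slope_vo2_min3", "calculated", "early_minutes", "slope of VO2 vs time within minute 3 [ml/min per min]"),
    def("slope_vo2_min4", "calculated", "early_minutes", "slope of VO2 vs time within minute 4 [ml/min per min]"),
    def("ve_min1", "calculated", "early_minutes", "mean minute ventilation during incremental minute 1 [l/min]")
  )
  stopifnot(nrow(reg) == 51L, sum(reg$class == "direct") == 12L,
            sum(reg$class == "calculated") == 39L, !anyDuplicated(reg$name))
  reg
}

#' Alias table for published feature spellings
#'
#' Maps the feature names as they appear in published tables (including
#' spelling variants such as "slop VCO2 versus VE") onto the canonical
#' registry names used throughout the package.
#'
#' @return Named character vector: names are published spellings, values are
#'   canonical registry names.
#' @export
feature_aliases <- function() {
  c("max time" = "max_time",
    "max VT" = "max_vt",
    "max VE" = "max_ve",
    "max VO2" = "max_vo2",
    "max VCO2" = "max_vco2",
    "max VO2 [ml/min/kg]" = "max_vo2_kg",
    "max RR" = "max_rr",
    "max RF" = "max_rf",
    "max speed" = "max_speed",
    "max slope" = "max_slope",
    "max HR" = "max_hr",
    "max RER" = "max_rer",
    "max VE/VO2" = "max_ve_vo2",
    "max VE/VCO2" = "max_ve_vco2",
    "slope VCO2 versus VE" = "slope_vco2_ve",
    "slop VCO2 versus VE" = "slope_vco2_ve",
    "slope VO2 versus VE" = "slope_vo2_ve",
    "max slope * max speed" = "max_slope_x_speed",
    "max slope time max speed" = "max_slope_x_speed",
    "max slope * max speed * max time" = "max_slope_x_speed_x_time",
    "VEmax/slope*speed" = "vemax_over_slope_speed",
    "VO2max/slope*speed" = "vo2max_over_slope_speed",
    "VO2max/(max slope * max speed)" = "vo2max_over_slope_speed",
    "predicted VO2" = "predicted_vo2",
    "Time at VAT" = "time_at_vat",
    "time to reach VAT" = "time_to_vat",
    "time from the VAT to the end" = "time_vat_to_end",
    "relative time of VAT" = "rel_time_vat",
    "ratio of VAT (VO2) to the max time" = "ratio_vat_vo2_max_time",
    "ratio of VAT to the max value of RER(VO2)" = "ratio_vat_rer_vo2",
    "Slope A" = "slope_a",
    "Slope B" = "slope_b",
    "area A of graph VO2 as a function of VCO2" = "area_a",
    "area B of graph VO2 as a function of VCO2" = "area_b",
    "VE at VAT" = "ve_at_vat",
    "VCO2 [ml/min] at VAT" = "vco2_at_vat",
    "VCO2-1 at VAT" = "vco2_1_at_vat",
    "VCO2-2 at VAT" = "vco2_2_at_vat",
    "VO2-1 at VAT" = "vo2_1_at_vat",
    "VO2-2 at VAT" = "vo2_2_at_vat",
    "VO2[ml/min/kg]at VAT" = "vo2_kg_at_vat",
    "VO2 [ml/min/kg] at VAT" = "vo2_kg_at_vat",
    "RF at VAT" = "rf_at_vat",
    "RR at VAT" = "rr_at_vat",
    "VSLOPE" = "vslope",
    "predicted VO2 at VAT/the real VO2 at VAT" = "pred_vo2_vat_ratio",
    "VO2 at 1st min" = "vo2_min1",
    "VO2 at 2nd min" = "vo2_min2",
    "VO2 at 3rd min" = "vo2_min3",
    "VO2 at 4th min" = "vo2_min4",
    "slope 1st min of VO2 vs. time" = "slope_vo2_min1",
    "slope at 1st min increase VO2" = "slope_vo2_min1",
    "slope at 2nd min increase VO2" = "slope_vo2_min2",
    "slope at 3rd min increase VO2" = "slope_vo2_min3",
    "slope at 4th min increase VO2" = "slope_vo2_min4",
    "VE at 1st min" = "ve_min1")
}

#' Resolve a published feature name to its canonical registry name
#'
#' @param name Character vector of feature names, canonical or published.
#' @param registry Feature registry (defaults to [feature_registry()]).
#' @return Character vector of canonical names.  Unresolvable names raise an
#'   error naming the offender.
#' @export
resolve_feature <- function(name, registry = feature_registry()) {
  aliases <- feature_aliases()
  out <- ifelse(name %in% registry$name, name,
                unname(aliases[name]))
  bad <- name[is.na(out)]
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  }
  out
}
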