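{
  "outcome": "pp_w",
  "intercept": 638.4,
  "terms": [
    {"feature": "max_ve", "coef": 170.3},
    {"feature": "max_rf", "coef": -43.5},
    {"feature": "max_vo2", "coef": -77.5},
    {"feature": "max_slope_x_speed", "coef": 98.6},
    {"feature": "slope_vco2_ve", "coef": 39.3},
    {"feature": "vo2max_over_slope_speed", "coef": 53}
  ],
  "provenance": {
    "source": "published multiple-regression equation for Wingate peak power from standardized CPET features",
    "note": "inputs are standardized feature values; evaluating at the all-zero vector returns the intercept"
  }
}
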