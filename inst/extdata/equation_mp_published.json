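{
  "outcome": "mp_w",
  "intercept": 476.8,
  "terms": [
    {"feature": "max_ve", "coef": 105.5},
    {"feature": "slope_vo2_min1", "coef": 36.4},
    {"feature": "max_vo2", "coef": -33.8},
    {"feature": "max_slope_x_speed", "coef": 27.6}
  ],
  "provenance": {
    "source": "published multiple-regression equation for Wingate mean power from standardized CPET features",
    "note": "inputs are standardized feature values; evaluating at the all-zero vector returns the intercept"
  }
}
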