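test_that("registry holds exactly 51 uniquely named features, 12 direct and 39 calculated", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 51L)
  expect_equal(sum(reg$class == "direct"), 12L)
  expect_equal(sum(reg$class == "calculated"), 39L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(reg$stage %in% c("full_test", "early_minutes")))
  expect_true(sum(reg$stage == "early_minutes") > 0)
})

test_that("published spellings resolve to registry names, including variants", {
  reg <- feature_registry()
  expect_equal(resolve_feature("slop VCO2 versus VE"), "slope_vco2_ve")
  expect_equal(resolve_feature("slope VCO2 versus VE"), "slope_vco2_ve")
  # max RF and max RR are distinct registry entries
  expect_equal(resolve_feature(c("max RF", "max RR")), c("max_rf", "max_rr"))
  # canonical names pass through unchanged
  expect_equal(resolve_feature("max_ve"), "max_ve")
  expect_error(resolve_feature("no such feature"), "unknown feature")
  # every alias lands on a registry entry
  expect_true(all(feature_aliases() %in% reg$name))
})
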