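test_that("test-volume counts extrapolate to whole-structure estimates", {
  expect_equal(extrapolate_total(63)$estimate, 554.4)
  expect_equal(extrapolate_total(63)$display, 554)
  expect_equal(extrapolate_total(70)$estimate, 616)
  expect_equal(extrapolate_total(0)$estimate, 0)
})

test_that("extrapolation is linear and reduces to identity", {
  s <- extrapolation_spec()
  expect_equal(extrapolate_total(126, s)$estimate,
               2 * extrapolate_total(63, s)$estimate)
  s2 <- extrapolation_spec(rostrocaudal_extent = 880)
  expect_equal(extrapolate_total(63, s2)$estimate,
               2 * extrapolate_total(63, s)$estimate)
  ident <- extrapolation_spec(sampled_depth = 100, rostrocaudal_extent = 100,
                              bilateral_factor = 1)
  expect_equal(extrapolate_total(41.7, ident)$estimate, 41.7)
})

test_that("extrapolation validates its arguments", {
  expect_error(extrapolation_spec(sampled_depth = 0), "sampled_depth")
  expect_error(extrapolation_spec(bilateral_factor = 3), "bilateral_factor")
  expect_error(extrapolate_total(-1), "mean_count")
})

test_that("summed labeling across days exceeds the constitutive reference", {
  expect_equal(labeling_sum_check(c(23, 38, 63, 26, 9), 70), 100 * 159 / 70)
  expect_gt(labeling_sum_check(c(23, 38, 63, 26, 9), 70), 100)
  expect_equal(labeling_sum_check(c(47, 30, 42, 38, 34), 92), 100 * 191 / 92)
  expect_gt(labeling_sum_check(c(47, 30, 42, 38, 34), 92), 100)
  expect_equal(labeling_sum_check(70, 70), 100)
  expect_error(labeling_sum_check(c(1, 2), 0), "> 0")
})
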