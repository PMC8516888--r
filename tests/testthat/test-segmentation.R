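test_that("scale calibration recovers the render scale from the ruler", {
  b <- render_ttc(ref_zones(900), seed = 21)
  calib <- calibrate_scale(b$image)
  expect_identical(calib$source, "ruler-detected")
  expect_lt(abs(calib$pixels_per_mm - 10) / 10, 0.01)
})

test_that("user-supplied scale bypasses detection; missing ruler is an error", {
  calib <- calibrate_scale(NULL, pixels_per_mm = 12.5)
  expect_identical(calib$pixels_per_mm, 12.5)
  expect_identical(calib$source, "user-supplied")
  blank <- array(0.8, dim = c(60, 60, 3))
  expect_error(calibrate_scale(blank), "no ruler")
})

test_that("area conversion is exact arithmetic", {
  calib <- calibrate_scale(NULL, pixels_per_mm = 10)
  expect_equal(measure_area(matrix(TRUE, 100, 100), calib), 1)
  expect_equal(measure_area(matrix(FALSE, 5, 5), calib), 0)
  expect_equal(measure_area(matrix(TRUE, 600, 600), calib), 36)
})

test_that("TTC segmentation recovers truth areas on noiseless and noisy renders", {
  z <- ref_zones(900)
  for (sigma in c(0, 8)) {
    b <- render_ttc(z, render_params(noise_sigma = sigma), seed = 31)
    seg <- segment_ttc(b$image, calibrate_scale(b$image))
    tol <- if (sigma == 0) 0.02 else 0.05
    expect_lt(abs(seg$areas[["white"]] - b$truth_areas[["ire"]]) /
                b$truth_areas[["ire"]], tol)
    expect_lt(abs(seg$areas[["red"]] - b$truth_areas[["re"]]) /
                b$truth_areas[["re"]], tol)
  }
})

test_that("a background-only image yields zero areas and a QC flag, not an error", {
  b <- render_ttc(ref_zones(900), seed = 41, ire_area_cm2 = 0,
                  re_area_cm2 = 0)
  seg <- segment_ttc(b$image, calibrate_scale(b$image))
  expect_identical(unname(seg$areas[["white"]]), 0)
  expect_identical(unname(seg$areas[["red"]]), 0)
  expect_true("empty-white" %in% seg$qc_flags)
})

test_that("melanin segmentation recovers truth on converged, absent, and star-distorted renders", {
  z <- ref_zones(1200)
  b48 <- render_melanin(z, 48, render_params(noise_sigma = 0), seed = 51,
                        star = NULL)
  seg <- segment_melanin(b48$image, calibrate_scale(b48$image))
  expect_lt(abs(seg$areas[["melanin"]] - b48$truth_areas[["melanin"]]) /
              b48$truth_areas[["melanin"]], 0.02)

  b0 <- render_melanin(z, 0, seed = 51)
  seg0 <- segment_melanin(b0$image, calibrate_scale(b0$image))
  expect_identical(unname(seg0$areas[["melanin"]]), 0)
  expect_true("empty-melanin" %in% seg0$qc_flags)

  bs <- render_melanin(z, 48, seed = 52, star = star_params(0.3, 5))
  segs <- segment_melanin(bs$image, calibrate_scale(bs$image))
  expect_lt(abs(segs$areas[["melanin"]] - bs$truth_areas[["melanin"]]) /
              bs$truth_areas[["melanin"]], 0.05)
})

test_that("segmentation is deterministic and reports cm2 independent of render scale", {
  z <- ref_zones(900)
  b <- render_ttc(z, seed = 61)
  calib <- calibrate_scale(b$image)
  s1 <- segment_ttc(b$image, calib)
  s2 <- segment_ttc(b$image, calib)
  expect_identical(s1$white_mask, s2$white_mask)
  expect_identical(s1$areas, s2$areas)

  b2 <- render_ttc(z, render_params(pixels_per_mm = 20), seed = 61)
  c2 <- calibrate_scale(b2$image)
  s3 <- segment_ttc(b2$image, c2)
  expect_gt(sum(b2$truth_ire_mask) / sum(b$truth_ire_mask), 3.5)
  expect_lt(abs(s3$areas[["white"]] - s1$areas[["white"]]) /
              s1$areas[["white"]], 0.02)
})

test_that("low-voltage two-lobe ablation areas are still fully recovered", {
  # at 300 V/cm the 250 V/cm super-level set splits into two lobes around
  # the electrodes; the component rule must keep both
  b <- render_ttc(ref_zones(300), seed = 71)
  seg <- segment_ttc(b$image, calibrate_scale(b$image))
  expect_true("multiple-components" %in% seg$qc_flags)
  expect_lt(abs(seg$areas[["white"]] - b$truth_areas[["ire"]]) /
              b$truth_areas[["ire"]], 0.05)
})
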