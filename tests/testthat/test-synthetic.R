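test_that("melanin kinetics follow the saturating exponential closed form", {
  kin <- kinetics_params()
  expect_identical(melanin_area_at(3, 0, kin), 0)
  expect_identical(melanin_area_at(3, kin$melanin_onset_h, kin), 0)
  expect_equal(melanin_area_at(3, kin$melanin_onset_h + kin$melanin_tau_h,
                               kin), 3 * (1 - exp(-1)))
  expect_equal(melanin_area_at(3, 1e6, kin), 3)
  expect_true(all(diff(melanin_area_at(3, seq(0, 48, by = 2), kin)) >= 0))
  expect_error(melanin_area_at(3, -1, kin), "non-negative")
})

test_that("deep-red decay follows the exponential closed form and vanishes by 21 h", {
  kin <- kinetics_params()
  expect_identical(red_area_at(2, 0, kin), 2)
  expect_equal(red_area_at(2, kin$red_decay_tau_h, kin), 2 * exp(-1))
  expect_equal(red_area_at(1, 21, kin), exp(-3.5))
  expect_lt(red_area_at(1, 21, kin), 0.05)
  expect_error(red_area_at(2, -0.1, kin), "non-negative")
})

test_that("noiseless TTC render uses exactly the nominal palette", {
  z <- ref_zones(900)
  p <- render_params(noise_sigma = 0)
  b <- render_ttc(z, p, seed = 3)
  cols <- unique(matrix(b$image, ncol = 3L))
  nominal <- rbind(p$background_color, p$white_core_color, p$deep_red_color,
                   c(0, 0, 0)) / 255
  expect_lte(nrow(cols), 4L)
  for (i in seq_len(nrow(cols)))
    expect_true(any(colSums(abs(t(nominal) - cols[i, ])) < 1e-12))
})

test_that("TTC truth areas equal the zone areas up to pixel quantization and are mask-consistent", {
  z <- ref_zones(1200)
  b <- render_ttc(z, seed = 11)
  ppm <- b$scale
  expect_equal(unname(b$truth_areas["ire"]), z$ire_area_cm2,
               tolerance = 1 / (100 * ppm^2) / z$ire_area_cm2)
  expect_equal(unname(b$truth_areas["re"]), z$re_area_cm2,
               tolerance = 1 / (100 * ppm^2) / z$re_area_cm2)
  # stored scalar equals recomputation from the stored mask exactly
  expect_identical(unname(b$truth_areas["ire"]),
                   sum(b$truth_ire_mask) / (100 * ppm^2))
  expect_identical(unname(b$truth_areas["re"]),
                   sum(b$truth_re_mask) / (100 * ppm^2))
  expect_false(any(b$truth_ire_mask & b$truth_re_mask))
  expect_identical(dim(b$image)[1:2], dim(b$truth_ire_mask))
})

test_that("renders are bit-identical under the same seed and differ under another", {
  z <- ref_zones(600)
  b1 <- render_ttc(z, seed = 5)
  b2 <- render_ttc(z, seed = 5)
  b3 <- render_ttc(z, seed = 6)
  expect_identical(b1$image, b2$image)
  expect_false(identical(b1$image, b3$image))
  m1 <- render_melanin(z, 12, seed = 5)
  m2 <- render_melanin(z, 12, seed = 5)
  expect_identical(m1$image, m2$image)
})

test_that("melanin renders follow the kinetics: zero at t=0, converged by 48 h, monotone", {
  z <- ref_zones(1500)
  kin <- kinetics_params()
  b0 <- render_melanin(z, 0, seed = 2)
  expect_identical(unname(b0$truth_areas["melanin"]), 0)
  b48 <- render_melanin(z, 48, seed = 2)
  expect_equal(unname(b48$truth_areas["melanin"]),
               melanin_area_at(z$ire_area_cm2, 48, kin), tolerance = 1e-3)
  # 48-h melanin area over TTC final area equals the kinetic fraction
  ratio <- unname(b48$truth_areas["melanin"]) / z$ire_area_cm2
  expect_equal(ratio, 1 - exp(-46 / 12), tolerance = 1e-3)
  expect_gt(ratio, 0.95)
  areas <- vapply(c(4, 8, 12, 24, 48), function(t)
    unname(render_melanin(z, t, seed = 2)$truth_areas["melanin"]), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("star distortion preserves area, is seed-deterministic, and validates inputs", {
  mask <- matrix(FALSE, 301, 301)
  xx <- rep(seq_len(301), each = 301) - 151
  yy <- rep(seq_len(301), times = 301) - 151
  mask[xx^2 + yy^2 <= 100^2] <- TRUE
  out <- apply_star_distortion(mask, 0.3, 5, seed = 9)
  expect_lt(abs(sum(out) - sum(mask)) / sum(mask), 0.03)
  expect_false(identical(out, mask))
  expect_identical(out, apply_star_distortion(mask, 0.3, 5, seed = 9))
  expect_identical(apply_star_distortion(mask, 0, 5, seed = 9), mask)
  expect_error(apply_star_distortion(mask, 1, 5), "amplitude")
  expect_error(apply_star_distortion(mask, 0.3, 2), "lobes")
})

test_that("generate_experiment has the declared cardinality and exact truth bookkeeping", {
  exp <- default_experiment()
  expect_length(exp$bundles, 30L)
  expect_identical(nrow(exp$truth), 30L)
  expect_identical(nrow(exp$measurements), 15L)
  # every bundle's stored truth area is recomputable from its stored mask
  for (id in names(exp$bundles)[c(1, 8, 16, 30)]) {
    b <- exp$bundles[[id]]
    mk <- grep("^truth_.*_mask$", names(b), value = TRUE)[1]
    expect_identical(unname(b$truth_areas[1]),
                     sum(b[[mk]]) / (100 * b$scale^2))
  }
  # truth IRE area strictly increasing across the five voltages (per rep)
  for (r in 1:3) {
    w <- exp$measurements$ttc_white_area_cm2[exp$measurements$rep == r]
    v <- exp$measurements$voltage_vcm[exp$measurements$rep == r]
    expect_true(all(diff(w[order(v)]) > 0))
  }
})

test_that("zero replicate noise collapses replicates; same master seed reproduces everything", {
  exp0 <- generate_experiment(kin = kinetics_params(rep_noise_cv = 0),
                              reps = 3, render = FALSE,
                              field_ref = ref_field(), master_seed = 4L)
  per_cond <- split(exp0$measurements$ttc_white_area_cm2,
                    exp0$measurements$voltage_vcm)
  for (a in per_cond) expect_identical(max(a), min(a))

  e1 <- generate_experiment(render = FALSE, field_ref = ref_field(),
                            master_seed = 7L)
  e2 <- generate_experiment(render = FALSE, field_ref = ref_field(),
                            master_seed = 7L)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$measurements, e2$measurements)
  expect_error(generate_experiment(conditions = data.frame()), "non-empty")
})

test_that("melanin and TTC bundles of one replicate share the same latent ablation area", {
  exp <- default_experiment()
  m <- exp$measurements
  # melanin at 12 h is the shared jittered final area times the kinetic
  # fraction, so the ratio is constant across conditions and replicates
  frac <- melanin_area_at(1, 12, kinetics_params())
  expect_equal(m$melanin_area_cm2 / m$ttc_white_area_cm2,
               rep(frac, nrow(m)), tolerance = 5e-3)
})
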