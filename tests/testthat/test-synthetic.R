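test_that("phantom generation is deterministic and validated", {
  p1 <- generate_phantom(phantom_spec(seed = 7))
  p2 <- generate_phantom(phantom_spec(seed = 7))
  expect_identical(p1$volume$data, p2$volume$data)
  p3 <- generate_phantom(phantom_spec(seed = 8))
  expect_false(identical(p1$volume$data, p3$volume$data))

  expect_error(phantom_spec(features = c(nose_length = 9)), "6 mm")
  expect_error(phantom_spec(features = c(unknown_thing = 1)), "unknown feature")
})

test_that("zero-deformation zero-noise phantom equals the canonical template", {
  p <- generate_phantom(phantom_spec(noise_sd = 0))
  expect_identical(p$volume$data, canonical_template()$data)
  expect_equal(p$landmarks$points, face_template_landmarks()$points)
})

test_that("planted feature deltas move their anchor landmarks exactly", {
  p <- generate_phantom(phantom_spec(features = c(nose_length = 4), noise_sd = 0))
  base <- face_template_landmarks()
  moved <- p$landmarks$points["nose_tip", ] - base$points["nose_tip", ]
  expect_equal(as.numeric(moved), c(0, 4, 0))

  pw <- generate_phantom(phantom_spec(features = c(nose_width = 3), noise_sd = 0))
  a0 <- anthropometrics(base)
  width0 <- a0$distance_mm[a0$measure == "nose_width"]
  widths <- anthropometrics(pw$landmarks)
  expect_equal(widths$distance_mm[widths$measure == "nose_width"], width0 + 3)
})

test_that("the stored true deformation reproduces the phantom volume", {
  p <- generate_phantom(phantom_spec(features = c(chin_protrusion = 3,
                                                  jaw_width = -4),
                                     noise_sd = 0, seed = 9))
  rec <- resample(canonical_template(), p$field)
  expect_gt(volume_ncc(rec, p$volume), 0.995)
})

test_that("cohorts honour planted scales and record coherent truth", {
  spec <- null_cohort_spec(13, n = 3, deformation_sd = 0, headsize_sd = 0,
                           noise_sd = 0)
  coh <- generate_cohort(spec)
  expect_equal(unname(coh$truth$headsize_true), rep(1, 3))
  expect_identical(coh$volumes[[1]]$data, coh$volumes[[2]]$data)

  sc <- c(0.95, 1, 1.05)
  spec2 <- null_cohort_spec(14, n = 3, deformation_sd = 0, noise_sd = 0,
                            headsize_scales = sc)
  coh2 <- generate_cohort(spec2)
  expect_equal(unname(coh2$truth$headsize_true), sc^3)
  # native-space landmarks are the scaled linear-space landmarks
  s3 <- coh2$truth$subjects[[3]]
  expect_equal(s3$landmarks_native$points, s3$landmarks_linear$points * 1.05)
  # the planted-scale subject volume matches a scaled template
  tmpl <- canonical_template()
  shrunk <- resample(tmpl, affine_from_matrix(diag(c(1 / 0.95, 1 / 0.95, 1 / 0.95, 1))))
  expect_gt(volume_ncc(coh2$volumes[[1]], shrunk), 0.999)
})

test_that("sex effects follow the female-positive convention", {
  spec <- cohort_spec(n_subjects = 40,
                      sex_effect = c(mouth_width = -3, lip_fullness = 1.5),
                      age_slope_male = setNames(numeric(0), character(0)),
                      age_slope_female = setNames(numeric(0), character(0)),
                      deformation_sd = 0, seed = 15)
  lc <- generate_landmark_cohort(spec, jitter_mm = 0)
  meas <- measure_cohort(lc)
  mw <- meas[meas$measure == "mouth_width", ]
  dat <- merge(mw, lc$covariates, by = "subject")
  gap <- mean(dat$distance_mm[dat$sex == "female"]) -
    mean(dat$distance_mm[dat$sex == "male"])
  expect_equal(gap, -3, tolerance = 0.3) # negative effect: larger in males
})
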