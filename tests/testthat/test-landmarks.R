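test_that("the shipped template has 56 uniquely named facial landmarks", {
  lms <- face_template_landmarks()
  expect_equal(length(lms$names), 56L)
  expect_equal(anyDuplicated(lms$names), 0L)
  expect_equal(lms$space, "model")
  # paired structures are mirrored across the midline
  expect_equal(lms$points["left_ala", ] * c(-1, 1, 1),
               lms$points["right_ala", ], ignore_attr = TRUE)
})

test_that("propagation through trivial fields is exact", {
  lms <- face_template_landmarks()
  aff <- diag(c(8, 8, 8, 1)); aff[1:3, 4] <- -32
  zero <- cranio_field(array(0, dim = c(9, 9, 9, 3)), aff)
  out <- propagate_landmarks(lms, zero)
  expect_equal(out$points, lms$points, ignore_attr = TRUE)
  expect_equal(out$space, "subject_linear")

  tdisp <- array(rep(c(3, -2, 1), each = 9^3), dim = c(9, 9, 9, 3))
  tf <- cranio_field(tdisp, aff)
  out2 <- propagate_landmarks(lms, tf)
  expect_equal(sweep(out2$points, 2, c(3, -2, 1)), lms$points, ignore_attr = TRUE)

  expect_error(propagate_landmarks(out, tf), "model space")
})

test_that("landmark errors are Euclidean, symmetric, and rigid-invariant", {
  lms <- face_template_landmarks()
  expect_equal(landmark_error(lms, lms)$distance_mm, rep(0, 56))

  shifted <- lms
  shifted$points["nose_tip", ] <- shifted$points["nose_tip", ] + c(3, 4, 0)
  err <- landmark_error(lms, shifted)
  expect_equal(err$distance_mm[err$name == "nose_tip"], 5)
  expect_equal(landmark_error(lms, shifted)$distance_mm,
               landmark_error(shifted, lms)$distance_mm)

  other <- landmark_set(c("a", "b"), matrix(0, 2, 3))
  expect_error(landmark_error(lms, other), "do not pair")

  # distances invariant under a global rigid motion
  rig <- affine_transform(rotations = c(0.4, -0.2, 0.7), translations = c(10, -5, 3))
  moved <- landmark_set(lms$names, transform_points(rig, lms$points))
  expect_equal(anthropometrics(moved)$distance_mm,
               anthropometrics(lms)$distance_mm, tolerance = 1e-9)
})

test_that("jittered manual landmarks reproduce the chi-distribution mean", {
  lms <- face_template_landmarks()
  set.seed(31)
  dists <- replicate(10, {
    manual <- landmark_set(lms$names, lms$points + matrix(rnorm(168), ncol = 3))
    mean(landmark_error(lms, manual)$distance_mm)
  })
  # E ||N3(0,1)|| = sqrt(2) * gamma(2) / gamma(3/2) ~= 1.596
  expect_lt(abs(mean(dists) - 1.5958) / 1.5958, 0.15)
})

test_that("anthropometric distances follow their specification", {
  lms <- face_template_landmarks()
  spec <- default_anthro_spec()
  out <- anthropometrics(lms, spec)
  expect_equal(nrow(out), 11L)
  # degenerate pair and a constructed axis-aligned pair
  degen <- data.frame(measure = "self", landmark_a = "nose_tip", landmark_b = "nose_tip")
  expect_equal(anthropometrics(lms, degen)$distance_mm, 0)
  two <- landmark_set(c("p", "q"), rbind(c(0, 0, 0), c(10, 0, 0)))
  ax <- data.frame(measure = "m", landmark_a = "p", landmark_b = "q")
  expect_equal(anthropometrics(two, ax)$distance_mm, 10)
  bad <- data.frame(measure = "m", landmark_a = "nose_tip", landmark_b = "nothere")
  expect_error(anthropometrics(lms, bad), "missing from the set")
})

test_that("anthropometric models recover a planted male-only age slope", {
  spec <- cohort_spec(n_subjects = 80,
                      sex_effect = setNames(numeric(0), character(0)),
                      age_slope_male = c(mouth_width = 0.06),
                      age_slope_female = setNames(numeric(0), character(0)),
                      deformation_sd = 0.5, seed = 77)
  lc <- generate_landmark_cohort(spec, jitter_mm = 0.5)
  meas <- measure_cohort(lc)
  fit <- fit_anthro_models(meas, lc$covariates)
  co <- fit$coefficients
  inter <- co[co$measure == "mouth_width" & co$term == "age_sex", ]
  expect_lt(inter$p, 0.05)
  # positive sex effects mean larger in females: a male-only growth slope
  # makes the interaction negative
  expect_lt(inter$estimate, 0)
  slopes <- fit$age_slopes
  male <- slopes[slopes$measure == "mouth_width" & slopes$sex == "male", ]
  expect_gt(0.06, male$ci_lo)
  expect_lt(0.06, male$ci_hi)

  const <- lc$covariates; const$sex <- "male"
  expect_error(fit_anthro_models(meas, const), "constant")
})

test_that("duplicating every subject inflates t by about sqrt(2)", {
  spec <- cohort_spec(n_subjects = 60, seed = 78, deformation_sd = 0.5)
  lc <- generate_landmark_cohort(spec)
  meas <- measure_cohort(lc)
  fit1 <- fit_anthro_models(meas, lc$covariates)
  meas2 <- meas; meas2$subject <- paste0(meas2$subject, "b")
  cov2 <- lc$covariates; cov2$subject <- paste0(cov2$subject, "b")
  fit2 <- fit_anthro_models(rbind(meas, meas2), rbind(lc$covariates, cov2))
  t1 <- fit1$coefficients$t[fit1$coefficients$term == "sex"]
  t2 <- fit2$coefficients$t[fit2$coefficients$term == "sex"]
  expect_equal(sign(t1), sign(t2))
  big <- abs(t1) > 2
  expect_lt(max(abs(t2[big] / t1[big] - sqrt(2))), 0.25)
})
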