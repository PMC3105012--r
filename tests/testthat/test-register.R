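test_that("schedules and optimiser settings are validated", {
  expect_error(nonlinear_schedule(numeric(0), integer(0), numeric(0)), "at least one")
  expect_error(nonlinear_schedule(c(4, 8), c(10, 10), c(4, 4)), "non-increasing")
  expect_error(nonlinear_schedule(c(8, 4), c(10, 10), c(4, 8)), "non-increasing")
  expect_error(nonlinear_schedule(8, 10, -1), "positive")
  sched <- full_schedule()
  expect_equal(sched$step_mm, c(8, 8, 4, 4, 2, 2))
  expect_equal(sched$iterations, c(30L, 30L, 30L, 30L, 10L, 10L))
  expect_equal(sched$blur_fwhm_mm, c(16, 8, 8, 4, 4, 2))
  cfg <- optimizer_config()
  expect_equal(c(cfg$stiffness, cfg$weight, cfg$similarity, cfg$search_radius_factor),
               c(1, 1, 0.3, 3))
})

test_that("self-registration returns the identity", {
  tmpl <- fix_template()
  fit <- register_linear(tmpl, tmpl, dof = 6)
  d <- decompose_affine(fit$matrix)
  expect_lt(max(abs(d$translations)), 0.1)
  expect_lt(max(abs(d$rotations)) * 180 / pi, 0.1)

  f <- register_nonlinear(tmpl, tmpl, phantom_schedule())
  rms <- sqrt(mean(rowSums(matrix(f$disp, ncol = 3)^2)))
  expect_lt(rms, 0.2)
})

test_that("known translations and scales are recovered", {
  tmpl <- fix_template()
  A <- affine_transform(translations = c(5, -3, 2))
  src <- resample(tmpl, A)
  fit <- register_linear(src, tmpl, dof = 6)
  resid <- fit$matrix %*% A$matrix # should be identity
  expect_lt(max(abs(resid[1:3, 4])), 0.5)

  A9 <- affine_transform(scales = c(1.10, 1.00, 0.95))
  src9 <- resample(tmpl, A9)
  fit9 <- register_linear(src9, tmpl, dof = 9)
  res9 <- decompose_affine(fit9$matrix %*% A9$matrix)
  expect_lt(max(abs(res9$scales - 1)), 0.02)
})

test_that("similarity is non-decreasing across nonlinear schedule steps", {
  tmpl <- fix_template()
  p <- generate_phantom(phantom_spec(features = c(chin_protrusion = 3,
                                                  nose_width = -2),
                                     noise_sd = 2, seed = 31))
  f <- register_nonlinear(tmpl, p$volume, phantom_schedule())
  expect_true(all(attr(f, "ncc") >= attr(f, "ncc_init") - 1e-6))
})
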