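grid_geometry <- function(n = 32) {
  aff <- diag(4); aff[1:3, 4] <- -(n - 1) / 2
  list(dim = rep(n, 3L), affine = aff)
}

world_points <- function(g) {
  idx <- as.matrix(expand.grid(x = seq_len(g$dim[1]) - 1,
                               y = seq_len(g$dim[2]) - 1,
                               z = seq_len(g$dim[3]) - 1))
  t((g$affine %*% rbind(t(idx), 1))[1:3, ])
}

test_that("Jacobian maps match closed forms", {
  g <- grid_geometry(24)
  zero <- cranio_field(array(0, dim = c(g$dim, 3)), g$affine)
  expect_equal(jacobian_map(zero)$data, array(1, dim = g$dim))

  # uniform linear field u(x) = (s-1) x, s = 1.1 -> det = 1.331 everywhere
  pts <- world_points(g)
  lin <- cranio_field(array(0.1 * pts, dim = c(g$dim, 3)), g$affine)
  jm <- jacobian_map(lin)
  interior <- jm$data[2:23, 2:23, 2:23]
  expect_equal(as.numeric(interior), rep(1.1^3, length(interior)), tolerance = 1e-9)
})

test_that("Jacobian of an analytic warp matches its symbolic determinant", {
  g <- grid_geometry(32)
  pts <- world_points(g)
  w <- 2 * pi / 40
  a <- c(1.5, 1.2, 1.8)
  u <- cbind(a[1] * sin(w * pts[, 2]), a[2] * sin(w * pts[, 3]),
             a[3] * sin(w * pts[, 1]))
  f <- cranio_field(array(u, dim = c(g$dim, 3)), g$affine)
  jm <- jacobian_map(f)
  # symbolic: J = I + offdiagonal(a1 w cos(w y), a2 w cos(w z), a3 w cos(w x))
  det_true <- 1 + prod(a) * w^3 * cos(w * pts[, 1]) * cos(w * pts[, 2]) * cos(w * pts[, 3])
  truth <- array(det_true, dim = g$dim)
  interior <- as.matrix(expand.grid(2:31, 2:31, 2:31))
  expect_lt(max(abs(jm$data[interior] - truth[interior])), 1e-3)
})

test_that("mean Jacobian of an affine map obeys change of variables", {
  g <- grid_geometry(24)
  pts <- world_points(g)
  sc <- c(1.05, 0.97, 1.02)
  u <- sweep(pts, 2, sc - 1, `*`)
  f <- cranio_field(array(u, dim = c(g$dim, 3)), g$affine)
  jm <- jacobian_map(f)
  expect_lt(abs(mean(jm$data[2:23, 2:23, 2:23]) - prod(sc)), 1e-3)
})

test_that("face mask respects the forehead plane and head support", {
  tmpl <- fix_template()
  full <- make_face_mask(tmpl, -31)
  expect_equal(sum(full$data), sum(craniomorph:::head_mask(tmpl)))
  expect_error(make_face_mask(tmpl, 40), "outside the model")
  expect_error(make_face_mask(tmpl, 30), "empty")

  face <- make_face_mask(tmpl, 0)
  lms <- face_template_landmarks()
  nose_vox <- round(world_to_voxel(tmpl, lms$points["nose_tip", , drop = FALSE])) + 1
  occiput_vox <- round(world_to_voxel(tmpl, matrix(c(0, -22, 0), 1))) + 1
  expect_equal(face$data[nose_vox[1], nose_vox[2], nose_vox[3]], 1)
  expect_equal(face$data[occiput_vox[1], occiput_vox[2], occiput_vox[3]], 0)
})

test_that("voxel-wise GLM equals the per-voxel regression oracle", {
  set.seed(21)
  n <- 16; g <- grid_geometry(12)
  vols <- lapply(1:n, function(i)
    cranio_volume(array(rnorm(prod(g$dim), mean = 1, sd = 0.1), dim = g$dim), g$affine))
  X <- cbind(intercept = 1, sex = sample(c(-0.5, 0.5), n, TRUE), age = rnorm(n))
  mask <- cranio_volume(array(1, dim = g$dim), g$affine)
  stat <- fit_glm(vols, X, c(0, 1, 0), mask, fwhm_mm = 4)
  expect_equal(stat$df, n - 3)
  for (v in sample(prod(g$dim), 100)) {
    y <- vapply(vols, function(vv) as.numeric(vv$data)[v], numeric(1))
    tref <- summary(lm(y ~ X[, 2] + X[, 3]))$coefficients[2, 3]
    expect_equal(as.numeric(stat$t$data)[v], tref, tolerance = 1e-10)
  }
})

test_that("flipping the sex coding flips the t map exactly", {
  set.seed(22)
  n <- 14; g <- grid_geometry(10)
  vols <- lapply(1:n, function(i)
    cranio_volume(array(rnorm(prod(g$dim)), dim = g$dim), g$affine))
  X <- cbind(1, sex_code(rep(c("male", "female"), length.out = n)), rnorm(n))
  mask <- cranio_volume(array(1, dim = g$dim), g$affine)
  s1 <- fit_glm(vols, X, c(0, 1, 0), mask, fwhm_mm = 4)
  X2 <- X; X2[, 2] <- -X[, 2]
  s2 <- fit_glm(vols, X2, c(0, 1, 0), mask, fwhm_mm = 4)
  expect_equal(s2$t$data, -s1$t$data)
})

test_that("degenerate designs and inputs are rejected", {
  set.seed(23)
  g <- grid_geometry(8)
  vols <- lapply(1:10, function(i)
    cranio_volume(array(rnorm(prod(g$dim)), dim = g$dim), g$affine))
  mask <- cranio_volume(array(1, dim = g$dim), g$affine)
  X <- cbind(a = 1, b = rnorm(10))
  Xr <- cbind(X, c = X[, "b"] * 2)
  expect_error(fit_glm(vols, Xr, c(0, 1, 0), mask), "rank deficient.*c")
  expect_error(fit_glm(vols, X, c(0, 1, 1), mask), "contrast length")
  expect_error(sex_code(c("male", "x")), "male/female")
  const <- matrix(1, 12, 125)
  expect_error(estimate_smoothness(const, array(TRUE, dim = c(5, 5, 5)),
                                   grid_geometry(5)), "constant residuals")
})

test_that("residual smoothness estimation tracks the applied blur", {
  set.seed(24)
  aff <- diag(4)
  crop <- 9:40
  vols8 <- lapply(1:20, function(i) {
    b <- gaussian_blur(cranio_volume(array(rnorm(48^3), dim = c(48, 48, 48))), 8)
    cranio_volume(b$data[crop, crop, crop], aff)
  })
  g <- grid_geometry(32)
  mask <- cranio_volume(array(1, dim = c(32, 32, 32)), aff)
  s8 <- fit_glm(vols8, cbind(1, rnorm(20)), c(0, 1), mask, fwhm_mm = 8)
  expect_gt(s8$fwhm_est_mm, 6.5)
  expect_lt(s8$fwhm_est_mm, 9.5)

  vols0 <- lapply(1:12, function(i)
    cranio_volume(array(rnorm(32^3), dim = c(32, 32, 32)), aff))
  s0 <- fit_glm(vols0, cbind(1, rnorm(12)), c(0, 1), mask, fwhm_mm = 8)
  expect_lt(s0$fwhm_est_mm, 2)
})

test_that("RFT thresholds are ordered and monotone in the search volume", {
  set.seed(25)
  n <- 24; g <- grid_geometry(24)
  vols <- lapply(1:n, function(i)
    gaussian_blur(cranio_volume(array(rnorm(prod(g$dim)), dim = g$dim), g$affine), 6))
  mask_full <- cranio_volume(array(1, dim = g$dim), g$affine)
  stat <- fit_glm(vols, cbind(1, rnorm(n)), c(0, 1), mask_full, fwhm_mm = 6)
  stat$fwhm_est_mm <- 6
  cl_full <- rft_correct(stat, alpha = 0.05)
  thr_full <- attr(cl_full, "threshold")
  expect_gte(thr_full, qt(1 - 0.025, stat$df))
  expect_lte(thr_full, qt(1 - 0.025 / sum(mask_full$data), stat$df))

  small <- array(0, dim = g$dim); small[8:16, 8:16, 8:16] <- 1
  stat_small <- stat; stat_small$mask <- cranio_volume(small, g$affine)
  thr_small <- attr(rft_correct(stat_small, alpha = 0.05), "threshold")
  expect_lt(thr_small, thr_full)

  stat_bad <- stat; stat_bad$df <- 2
  expect_error(rft_correct(stat_bad), "df > 2")
})

test_that("a planted strong effect yields one cluster at the planted centre", {
  set.seed(26)
  n <- 40; g <- grid_geometry(32)
  pts <- world_points(g)
  bump <- array(exp(-rowSums(sweep(pts, 2, c(5, -3, 2))^2) / (2 * 4^2)), dim = g$dim)
  grp <- rep(c(-0.5, 0.5), each = n / 2)
  vols <- lapply(1:n, function(i) {
    noise <- gaussian_blur(cranio_volume(array(rnorm(prod(g$dim), sd = 0.05),
                                               dim = g$dim), g$affine), 6)
    cranio_volume(1 + 0.4 * grp[i] * bump + noise$data, g$affine)
  })
  X <- cbind(1, grp)
  mask <- cranio_volume(array(1, dim = g$dim), g$affine)
  stat <- fit_glm(vols, X, c(0, 1), mask, fwhm_mm = 6)
  cl <- rft_correct(stat, alpha = 0.05)
  expect_equal(nrow(cl), 1)
  expect_lt(sqrt(sum((c(cl$peak_x[1], cl$peak_y[1], cl$peak_z[1]) - c(5, -3, 2))^2)), 5)
  expect_lt(cl$p_corrected[1], 0.05)
})
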