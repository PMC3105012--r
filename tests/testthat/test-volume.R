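test_that("NIfTI round trip preserves data and affine", {
  set.seed(1)
  aff <- diag(4); aff[1:3, 4] <- c(-7.5, -7.5, -7.5); aff[1, 1] <- 1.25
  vol <- cranio_volume(array(rnorm(16^3), dim = c(16, 16, 16)), aff)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  # float32 storage: values survive a float round trip exactly when compared
  # as float32
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-4)
  unlink(f)
})

test_that("reading rejects missing files and non-3D volumes", {
  expect_error(read_volume(tempfile()), "no such file")
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(8, 8, 8, 2))), f)
  expect_error(read_volume(f), "3D")
  unlink(f)
})

test_that("generated phantom reads back with generator geometry", {
  p <- generate_phantom(phantom_spec(seed = 2))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(p$volume, f)
  back <- read_volume(f)
  expect_equal(dim(back$data), c(64L, 64L, 64L))
  expect_equal(voxel_size(back), c(1, 1, 1), tolerance = 1e-5)
  unlink(f)
})

test_that("world/voxel coordinate round trip is exact", {
  aff <- diag(c(1.5, 1, 2, 1)); aff[1:3, 4] <- c(-10, 3, -5)
  aff[1:3, 1:3] <- aff[1:3, 1:3] %*% rotation_3d(0.3)
  vol <- cranio_volume(array(0, dim = c(8, 8, 8)), aff)
  set.seed(3)
  pts <- matrix(runif(30, -20, 20), ncol = 3)
  back <- voxel_to_world(vol, world_to_voxel(vol, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("resampling handles identity, lattice shifts and singularity", {
  tmpl <- fix_template()
  out <- resample(tmpl, NULL, geometry(tmpl))
  expect_equal(out$data, tmpl$data)

  tr <- affine_transform(translations = c(1, 0, 0))
  sh <- resample(tmpl, tr)
  expect_equal(sh$data[1:63, , ], tmpl$data[2:64, , ])
  expect_true(all(sh$data[64, , ] == 0))

  sing <- affine_from_matrix(diag(4)); sing$matrix[1, 1] <- 0
  expect_error(resample(tmpl, sing), "singular")
})

test_that("resampling is linear in intensities", {
  set.seed(4)
  a <- cranio_volume(array(rnorm(16^3), dim = c(16, 16, 16)))
  b <- cranio_volume(array(rnorm(16^3), dim = c(16, 16, 16)))
  tr <- affine_transform(rotations = c(0.1, 0, 0.05), translations = c(0.7, -0.3, 0.2))
  mix <- cranio_volume(2 * a$data - 3 * b$data, a$affine)
  lhs <- resample(mix, tr)$data
  rhs <- 2 * resample(a, tr)$data - 3 * resample(b, tr)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("fractional shifts track the analytic phantom", {
  vol <- gaussian_phantom(32, sigma = 6)
  half <- affine_transform(translations = c(0.5, 0, 0))
  once <- resample(resample(vol, half), half)
  full <- resample(vol, affine_transform(translations = c(1, 0, 0)))
  # compare both against the analytic truth: G shifted by 1 voxel
  co <- seq(-15.5, 15.5, 1)
  g <- expand.grid(x = co, y = co, z = co)
  truth <- array(exp(-((g$x + 1)^2 + g$y^2 + g$z^2) / 72), dim = c(32, 32, 32))
  # trilinear error bound per pass: h^2/8 * max|f''| = 1/(8 sigma^2) ~ 0.0035
  interior <- as.matrix(expand.grid(3:30, 3:30, 3:30))
  expect_lt(max(abs(full$data[interior] - truth[interior])), 0.004)
  expect_lt(max(abs(once$data[interior] - truth[interior])), 0.008)
  expect_lt(max(abs(once$data[interior] - full$data[interior])), 0.008)
})

test_that("gaussian blur conserves intensity and fixes constants", {
  blob <- gaussian_phantom(40, sigma = 3)
  out <- gaussian_blur(blob, 8)
  expect_lt(abs(sum(out$data) / sum(blob$data) - 1), 0.001)

  const <- cranio_volume(array(7, dim = c(20, 20, 20)))
  expect_equal(gaussian_blur(const, 4)$data[9:12, 9:12, 9:12],
               const$data[9:12, 9:12, 9:12], tolerance = 1e-6)
  expect_error(gaussian_blur(const, 0), "positive")
})

test_that("blurred delta matches the closed-form 3D Gaussian", {
  n <- 33
  dat <- array(0, dim = c(n, n, n)); dat[17, 17, 17] <- 1
  vol <- cranio_volume(dat)
  out <- gaussian_blur(vol, 8)
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 3.39728, tolerance = 1e-4)
  co <- seq(-16, 16, 1)
  g <- expand.grid(x = co, y = co, z = co)
  r2 <- g$x^2 + g$y^2 + g$z^2
  truth <- array(exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)^1.5, dim = c(n, n, n))
  sel <- which(array(sqrt(r2), dim = c(n, n, n)) <= 2 * sigma)
  expect_lt(max(abs(out$data[sel] - truth[sel]) / truth[17, 17, 17]), 0.01)
})

test_that("blur cascade is equivalent to a single wider blur", {
  blob <- gaussian_phantom(32, sigma = 4)
  two <- gaussian_blur(gaussian_blur(blob, 5), 6)
  one <- gaussian_blur(blob, sqrt(5^2 + 6^2))
  rel_rms <- sqrt(mean((two$data - one$data)^2)) / sqrt(mean(one$data^2))
  expect_lt(rel_rms, 0.01)
})
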