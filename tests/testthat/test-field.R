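smooth_test_field <- function(seed, rms = 2) {
  set.seed(seed)
  craniomorph:::random_smooth_field(64, rms_mm = rms)
}

test_that("field evaluation equals manual trilinear interpolation", {
  f <- smooth_test_field(1)
  d <- dim(f$disp)[1:3]
  set.seed(2)
  for (rep in 1:5) {
    v <- runif(3, 0.6, d - 1.6) # 0-based fractional voxel coordinate
    w <- as.numeric(f$affine %*% c(v, 1))[1:3]
    got <- eval_field(f, matrix(w, 1))$disp
    lo <- floor(v); fr <- v - lo
    manual <- numeric(3)
    for (c in 1:3) {
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wgt <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
        acc <- acc + wgt * f$disp[lo[1] + dx + 1, lo[2] + dy + 1, lo[3] + dz + 1, c]
      }
      manual[c] <- acc
    }
    expect_equal(as.numeric(got), manual, tolerance = 1e-12)
  }
})

test_that("composition satisfies identity and associativity", {
  tmpl <- fix_template()
  a <- affine_transform(rotations = c(0.04, 0, -0.03), translations = c(2, -1, 3))
  idf <- compose_transforms(a, invert_affine(a), lattice = geometry(tmpl))
  expect_lt(max(abs(idf$disp)), 1e-9)

  f <- smooth_test_field(3)
  idc <- compose_transforms(affine_transform(), f)
  expect_equal(idc$disp, f$disp, tolerance = 1e-9)

  g <- smooth_test_field(4, rms = 1.5)
  h <- smooth_test_field(5, rms = 1)
  set.seed(6)
  pts <- matrix(runif(60, -20, 20), ncol = 3)
  left <- compose_transforms(compose_transforms(f, g), h)
  right <- compose_transforms(f, compose_transforms(g, h))
  expect_lt(max(abs(transform_points(left, pts) - transform_points(right, pts))), 0.1)
})

test_that("field inversion handles trivial and smooth cases", {
  tmpl <- fix_template()
  z <- zero_like <- cranio_field(array(0, dim = c(9, 9, 9, 3)),
                                 diag(c(8, 8, 8, 1)))
  expect_equal(invert_field(z)$disp, z$disp)

  tdisp <- array(rep(c(2, -1, 0.5), each = 9^3), dim = c(9, 9, 9, 3))
  tf <- cranio_field(tdisp, diag(c(8, 8, 8, 1)))
  expect_equal(invert_field(tf)$disp, -tdisp, tolerance = 1e-9)

  f <- smooth_test_field(7, rms = 1.5)
  inv <- invert_field(f, tol_mm = 0.02, max_iter = 40)
  # composition residual at the nodes
  comp <- compose_transforms(f, inv)
  mag <- sqrt(rowSums(matrix(comp$disp, ncol = 3)^2))
  expect_lt(median(mag), 0.05)
  # double inversion returns the field within 2x tolerance
  back <- invert_field(inv, tol_mm = 0.02, max_iter = 40)
  expect_lt(median(abs(back$disp - f$disp)), 0.04)
})

test_that("non-diffeomorphic fields are rejected", {
  n <- 9
  co <- (seq_len(n) - 1) * 8 - 32
  fold <- array(0, dim = c(n, n, n, 3))
  fold[, , , 1] <- -2 * outer(co, rep(1, n * n)) # u_x = -2x: det(1-2) < 0
  f <- cranio_field(fold, diag(c(8, 8, 8, 1)))
  expect_error(invert_field(f), "not invertible")
})

test_that("displacement fields survive NIfTI serialisation", {
  f <- smooth_test_field(8)
  path <- tempfile(fileext = ".nii.gz")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$disp, f$disp, tolerance = 1e-6)
  expect_equal(back$affine, f$affine, tolerance = 1e-4)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
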