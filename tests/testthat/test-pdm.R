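test_that("degenerate and rank-one cohorts decompose exactly", {
  lms <- face_template_landmarks()
  same <- lapply(1:5, function(i) landmark_set(lms$names, lms$points, "subject_linear"))
  names(same) <- paste0("s", 1:5)
  p0 <- fit_pdm(same, lms)
  expect_lt(max(p0$eigenvalues), 1e-20)
  expect_lt(max(abs(p0$scores)), 1e-10)

  set.seed(41)
  v <- matrix(rnorm(168), ncol = 3); v <- v / sqrt(sum(v^2))
  sets <- lapply(1:20, function(i)
    landmark_set(lms$names, lms$points + rnorm(1, 0, 3) * v, "subject_linear"))
  names(sets) <- paste0("s", 1:20)
  p1 <- fit_pdm(sets, lms)
  expect_gt(p1$eigenvalues[1] / p1$total_variance, 1 - 1e-10)
  cosv <- abs(sum(p1$eigenvectors[, 1] * as.numeric(t(v))))
  expect_gt(cosv, 0.999)
})

test_that("planted orthogonal modes are recovered with correct variances", {
  pm <- planted_mode_sets(100, c(4, 2, 1), seed = 42)
  p3 <- fit_pdm(pm$sets, pm$reference)
  ratios <- p3$eigenvalues[1:3] / p3$eigenvalues[3]
  expect_equal(ratios, c(16, 4, 1), tolerance = 0.25)
  ang <- acos(pmin(1, min(svd(t(p3$eigenvectors[, 1:3]) %*% pm$modes)$d))) * 180 / pi
  expect_lt(ang, 10)

  # reconstruction at full rank and score-variance identity
  X <- t(vapply(pm$sets, function(s) as.numeric(t(s$points)), numeric(168)))
  Xc <- sweep(X, 2, p3$mean_reference)
  expect_lt(max(abs(p3$scores %*% t(p3$eigenvectors) - Xc)), 1e-8)
  expect_equal(apply(p3$scores[, 1:3], 2, function(s) sum(s^2) / 99),
               p3$eigenvalues[1:3], tolerance = 1e-6)
  # orthonormal eigenvectors, descending non-negative eigenvalues
  expect_lt(max(abs(crossprod(p3$eigenvectors) - diag(ncol(p3$eigenvectors)))), 1e-8)
  expect_true(all(diff(p3$eigenvalues) <= 1e-12))
  expect_true(all(p3$eigenvalues >= 0))
  # cumulative variance non-decreasing, reaching 1 at full rank
  expect_true(all(diff(p3$cumulative_variance) >= 0))
  expect_equal(p3$cumulative_variance[length(p3$cumulative_variance)], 1,
               tolerance = 1e-6)
})

test_that("PC-score models recover planted trends and sign conventions", {
  spec <- cohort_spec(n_subjects = 90,
                      sex_effect = setNames(numeric(0), character(0)),
                      age_slope_male = c(jaw_width = 0.08),
                      age_slope_female = setNames(numeric(0), character(0)),
                      deformation_sd = 0.3, seed = 44)
  lc <- generate_landmark_cohort(spec, jitter_mm = 0.3)
  pdm <- fit_pdm(lc$landmark_sets, face_template_landmarks())
  res <- analyze_scores(pdm, lc$covariates, n_pcs = 3)
  inter <- res$coefficients[res$coefficients$term == "age_sex", ]
  expect_lt(min(inter$p), 0.01) # the planted male-only slope loads on a PC
  pc_hit <- inter$pc[which.min(inter$p)]
  slopes <- res$age_slopes
  expect_lt(slopes$p[slopes$pc == pc_hit & slopes$sex == "male"], 0.01)
})

test_that("body-fat residualisation attenuates a collinear sex effect", {
  set.seed(45)
  n <- 120
  sex <- rep(c("male", "female"), n / 2)
  sexc <- sex_code(sex)
  age <- runif(n, 144, 216)
  bodyfat <- 21 + 8 * sexc + rnorm(n, 0, 1)  # nearly collinear with sex
  pm <- planted_mode_sets(n, c(3, 1), seed = 46)
  # inject a sex effect along mode 1
  sets <- lapply(seq_len(n), function(i) {
    s <- pm$sets[[i]]
    landmark_set(s$names, s$points + matrix(4 * sexc[i] * pm$modes[, 1],
                                            ncol = 3, byrow = TRUE), s$space)
  })
  names(sets) <- names(pm$sets)
  pdm <- fit_pdm(sets, pm$reference)
  cov <- data.frame(subject = names(sets), sex = sex, age_months = age,
                    bodyfat_pct = bodyfat)
  raw <- analyze_scores(pdm, cov, n_pcs = 1)
  resid <- analyze_scores(pdm, cov, n_pcs = 1, residualize_bodyfat = TRUE)
  b_raw <- raw$coefficients$estimate[raw$coefficients$term == "sex"]
  b_res <- resid$coefficients$estimate[resid$coefficients$term == "sex"]
  # partial-regression algebra: regressing out a proxy of sex shrinks the
  # sex coefficient toward zero
  expect_lt(abs(b_res), 0.35 * abs(b_raw))

  cov2 <- cov[, setdiff(names(cov), "bodyfat_pct")]
  expect_error(analyze_scores(pdm, cov2, residualize_bodyfat = TRUE), "bodyfat")
})

test_that("thin-plate splines interpolate, reproduce affines, and bend", {
  lms <- face_template_landmarks()
  ident <- tps_fit(lms, lms)
  set.seed(47)
  pts <- matrix(runif(60, -25, 25), ncol = 3)
  expect_lt(max(abs(tps_apply(ident, pts) - pts)), 1e-8)

  tgt <- landmark_set(lms$names, lms$points + matrix(rnorm(168, 0, 2), ncol = 3))
  w <- tps_fit(lms, tgt)
  expect_lt(max(abs(tps_apply(w, lms$points) - tgt$points)), 1e-6)
  expect_gt(tps_bending_energy(w), 1e-3)

  A <- affine_transform(rotations = c(0.1, 0.05, -0.08), translations = c(3, -2, 1),
                        scales = c(1.1, 0.9, 1.05))
  tgt2 <- landmark_set(lms$names, transform_points(A, lms$points))
  w2 <- tps_fit(lms, tgt2)
  expect_lt(max(abs(w2$weights)), 1e-9)
  expect_lt(max(abs(tps_apply(w2, pts) - transform_points(A, pts))), 1e-8)
  expect_lt(abs(tps_bending_energy(w2)), 1e-12)

  dup <- landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(tps_fit(dup, dup), "duplicate")
})

test_that("PC simulation scales linearly and rejects degenerate modes", {
  pm <- planted_mode_sets(50, c(4, 2, 1), seed = 48)
  p3 <- fit_pdm(pm$sets, pm$reference)
  sims <- simulate_pc(p3, 1)
  expect_equal(vapply(sims, `[[`, numeric(1), "proportion"), c(0.2, 0.4, 0.6, 0.8, 1))
  ref <- matrix(p3$mean_reference, ncol = 3, byrow = TRUE)
  d_full <- sims[[5]]$landmarks$points - ref
  for (k in 1:4) {
    dk <- sims[[k]]$landmarks$points - ref
    expect_lt(max(abs(dk - sims[[k]]$proportion * d_full)), 1e-9)
  }
  # full displacement magnitude equals amplitude_sd * sqrt(eigenvalue)
  expect_equal(sqrt(sum(d_full^2)), 3 * sqrt(p3$eigenvalues[1]), tolerance = 1e-9)
  # the simulated direction is the planted dominant mode
  cosm <- abs(sum(as.numeric(t(d_full)) / sqrt(sum(d_full^2)) *
                    p3$eigenvectors[, 1]))
  expect_gt(cosm, 1 - 1e-9)
  # warps map the reference onto the displaced landmarks
  expect_lt(max(abs(tps_apply(sims[[3]]$warp, ref) - sims[[3]]$landmarks$points)), 1e-6)

  expect_error(simulate_pc(p3, 50), "outside the model rank")
  same <- lapply(1:4, function(i) landmark_set(pm$reference$names,
                                               pm$reference$points, "subject_linear"))
  names(same) <- paste0("s", 1:4)
  flat <- fit_pdm(same, pm$reference)
  expect_error(simulate_pc(flat, 1), "zero eigenvalue")
})

test_that("PDM serialisation writes the four component tables", {
  pm <- planted_mode_sets(10, c(2, 1), seed = 49)
  p <- fit_pdm(pm$sets, pm$reference)
  dir <- tempfile()
  write_pdm(p, dir)
  expect_true(all(file.exists(file.path(dir, c("mean.tsv", "eigenvectors.tsv",
                                               "eigenvalues.tsv", "scores.tsv")))))
  unlink(dir, recursive = TRUE)
})
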