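# Shared fixtures. Everything is generated in code; expensive objects are
# built once per test run and cached in this environment.
.fix <- new.env()

fix_template <- function() {
  if (is.null(.fix$template)) .fix$template <- canonical_template()
  .fix$template
}

rotation_3d <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
}

# analytic isotropic Gaussian blob, for interpolation-error oracles
gaussian_phantom <- function(n = 32, sigma = 6, centre = c(0, 0, 0)) {
  half <- (n - 1) / 2
  co <- seq(-half, half, by = 1)
  g <- expand.grid(x = co, y = co, z = co)
  vals <- exp(-((g$x - centre[1])^2 + (g$y - centre[2])^2 +
                  (g$z - centre[3])^2) / (2 * sigma^2))
  cranio_volume(array(vals, dim = c(n, n, n)))
}

# zero-effect cohort spec for calibration work
null_cohort_spec <- function(seed, n = 60, deformation_sd = 1, ...) {
  cohort_spec(n_subjects = n,
              sex_effect = setNames(numeric(0), character(0)),
              age_slope_male = setNames(numeric(0), character(0)),
              age_slope_female = setNames(numeric(0), character(0)),
              deformation_sd = deformation_sd, seed = seed, ...)
}

# long-format anthropometric measures for a landmark cohort
measure_cohort <- function(lc) {
  do.call(rbind, lapply(names(lc$landmark_sets), function(id)
    cbind(subject = id, anthropometrics(lc$landmark_sets[[id]]))))
}

# exact-variance planted-mode landmark cohort: k orthonormal modes with
# whitened coefficient draws, so the sample covariance of the coefficients is
# exactly diag(sds^2)
planted_mode_sets <- function(n, sds, seed) {
  lms <- face_template_landmarks()
  set.seed(seed)
  k <- length(sds)
  vs <- qr.Q(qr(matrix(rnorm(168 * k), ncol = k)))
  C <- matrix(rnorm(n * k), ncol = k)
  C <- scale(C, center = TRUE, scale = FALSE)
  C <- C %*% solve(chol(cov(C))) %*% diag(sds, k)
  sets <- lapply(seq_len(n), function(i)
    landmark_set(lms$names, lms$points + matrix(vs %*% C[i, ], ncol = 3, byrow = TRUE),
                 "subject_linear"))
  names(sets) <- sprintf("s%03d", seq_len(n))
  list(sets = sets, modes = vs, sds = sds, reference = lms)
}
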