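#' Synthetic brain-stripped head phantoms with full ground truth
#'
#' The generator emulates the input the pipeline expects from real data -
#' brain-stripped T1-weighted head volumes on a 1 mm grid - as a canonical
#' analytic head (ellipsoid with a removed brain cavity, a brightened skull
#' shell, and nose / lip / chin / brow / ear / zygomatic structures built
#' from smooth analytic shapes) deformed per subject by (i) compactly
#' supported displacement kernels attached to named facial features, (ii) a
#' smooth random warp, and (iii) a global head-size scaling. Because every
#' subject is literally a warp of the canonical template, the generator can
#' return the exact deformation, the exact landmark positions and every
#' planted covariate effect, making each pipeline stage testable without any
#' cohort data.
#'
#' Feature displacement kernels have a flat plateau (radius `r0`) around
#' their anchor landmarks and decay smoothly to zero at a support radius
#' `R`, so a planted feature delta moves its own anchor landmarks by exactly
#' the planted amount while staying invertible.
#'
#' @name synthetic_data
NULL

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# feature table: anchors (world mm, canonical space), unit directions,
# per-anchor share of the planted delta, plateau r0 and support R (mm)
feature_table <- function() {
  list(
    nose_length = list(anchors = rbind(c(0, 23, -5)),
                       dirs = rbind(c(0, 1, 0)), share = 1, r0 = 2.5, R = 9),
    nose_width = list(anchors = rbind(c(3.5, 20.5, -7), c(-3.5, 20.5, -7)),
                      dirs = rbind(c(1, 0, 0), c(-1, 0, 0)), share = 0.5,
                      r0 = 1.5, R = 5.5),
    chin_protrusion = list(anchors = rbind(c(0, 16, -19)),
                           dirs = rbind(c(0, 1, 0)), share = 1, r0 = 2.5, R = 9),
    jaw_width = list(anchors = rbind(c(15, 2, -16), c(-15, 2, -16)),
                     dirs = rbind(c(1, 0, 0), c(-1, 0, 0)), share = 0.5,
                     r0 = 3, R = 10),
    lip_fullness = list(anchors = rbind(c(0, 17, -13)),
                        dirs = rbind(c(0, 1, 0)), share = 1, r0 = 2.5, R = 8),
    mouth_width = list(anchors = rbind(c(8, 16, -13), c(-8, 16, -13)),
                       dirs = rbind(c(1, 0, 0), c(-1, 0, 0)), share = 0.5,
                       r0 = 2, R = 7),
    forehead_slope = list(anchors = rbind(c(0, 19, 8)),
                          dirs = rbind(c(0, 1, 0)), share = 1, r0 = 3, R = 10))
}

#' @rdname synthetic_data
#' @return `feature_names()` lists the facial features a phantom or cohort
#'   spec may perturb.
#' @export
feature_names <- function() names(feature_table())

# plateau kernel: 1 for r <= r0, quartic decay to 0 at R
plateau_kernel <- function(r, r0, R) {
  s <- pmin(pmax((r - r0) / (R - r0), 0), 1)
  (1 - s^2)^2
}

# analytic forward displacement of the planted features at arbitrary points
feature_displacement <- function(points, deltas) {
  pts <- matrix(as.numeric(points), ncol = 3)
  out <- matrix(0, nrow(pts), 3)
  ft <- feature_table()
  for (f in names(deltas)) {
    d <- deltas[[f]]
    if (is.na(d) || d == 0) next
    spec <- ft[[f]]
    for (a in seq_len(nrow(spec$anchors))) {
      r <- sqrt(rowSums(sweep(pts, 2, spec$anchors[a, ])^2))
      k <- plateau_kernel(r, spec$r0, spec$R)
      out <- out + (d * spec$share) * outer(k, spec$dirs[a, ])
    }
  }
  out
}

# smooth membership helpers for the template
smooth_in <- function(d, width) stats::plogis(d / width)

dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  t <- pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                  (pts[, 3] - a[3]) * ab[3]) / sum(ab^2), 0), 1)
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]; pz <- a[3] + t * ab[3]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2 + (pts[, 3] - pz)^2)
}

.template_cache <- new.env(parent = emptyenv())

#' @rdname synthetic_data
#' @param points n x 3 matrix of world coordinates (mm).
#' @return `template_intensity()` evaluates the canonical head's analytic
#'   intensity at arbitrary world points, allowing exactly warped phantoms
#'   with no interpolation.
#' @export
template_intensity <- function(points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]

  q_head <- sqrt((x / 20)^2 + ((y + 3) / 22)^2 + (z / 25)^2)
  head <- smooth_in(1 - q_head, 0.05)
  q_cav <- sqrt((x / 15)^2 + ((y + 7) / 15)^2 + ((z - 6) / 15)^2)
  cavity <- smooth_in(1 - q_cav, 0.06)
  shell <- exp(-((q_head - 0.88) / 0.06)^2)

  I <- 100 * head * (1 - 0.8 * cavity) + 25 * shell * head
  add <- function(I, dist, radius, amp, width = 1) I + amp * smooth_in(radius - dist, width)
  I <- add(I, dist_to_segment(pts, c(0, 17, 4), c(0, 23, -5)), 3.5, 45)      # nose
  I <- add(I, dist_to_segment(pts, c(-8, 16.5, -13), c(8, 16.5, -13)), 2.8, 35) # lips
  I <- add(I, dist_to_segment(pts, c(-8, 16.8, -13), c(8, 16.8, -13)), 0.8, -25, 0.5) # lip seam
  I <- add(I, sqrt(x^2 + (y - 15)^2 + (z + 20)^2), 4, 40)                    # chin
  I <- add(I, dist_to_segment(pts, c(-9, 18, 8), c(9, 18, 8)), 3, 30)        # brow
  I <- add(I, sqrt((x - 21)^2 + (y + 3)^2 + (z + 5)^2), 4.5, 35)             # ears
  I <- add(I, sqrt((x + 21)^2 + (y + 3)^2 + (z + 5)^2), 4.5, 35)
  I <- add(I, dist_to_segment(pts, c(18, 6, 0), c(14, 12, -2)), 2.5, 30)     # zygoma
  I <- add(I, dist_to_segment(pts, c(-18, 6, 0), c(-14, 12, -2)), 2.5, 30)
  I <- add(I, sqrt((x - 8)^2 + (y - 16.5)^2 + (z - 3)^2), 2.8, -45)          # orbits
  I <- add(I, sqrt((x + 8)^2 + (y - 16.5)^2 + (z - 3)^2), 2.8, -45)
  pmax(I, 0)
}

#' @rdname synthetic_data
#' @param grid_size Cubic grid side in voxels (1 mm isotropic, world origin
#'   at the grid centre).
#' @return `canonical_template()` returns the canonical head phantom as a
#'   [cranio_volume].
#' @export
canonical_template <- function(grid_size = 64) {
  key <- as.character(grid_size)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  n <- grid_size
  half <- (n - 1) / 2
  co <- seq(-half, half, by = 1)
  g <- expand.grid(x = co, y = co, z = co)
  vol <- cranio_volume(array(template_intensity(as.matrix(g)), dim = c(n, n, n)))
  .template_cache[[key]] <- vol
  vol
}

#' @rdname synthetic_data
#' @param features Named numeric vector of feature deltas (mm); names from
#'   [feature_names()]; absolute values capped at 6 mm to stay anatomically
#'   plausible and invertible.
#' @param noise_sd Additive Gaussian intensity noise (arbitrary units; the
#'   template's soft tissue is ~100).
#' @param bias_field Multiply by a gentle linear intensity gradient,
#'   mimicking residual inhomogeneity.
#' @param seed RNG seed; the same spec and seed give a bit-identical phantom.
#' @return `phantom_spec()` returns a validated spec list.
#' @export
phantom_spec <- function(grid_size = 64, features = NULL, noise_sd = 3,
                         bias_field = FALSE, seed = 1L) {
  features <- check_features(features)
  stopifnot(grid_size >= 16, noise_sd >= 0)
  list(grid_size = as.integer(grid_size), features = features,
       noise_sd = noise_sd, bias_field = isTRUE(bias_field),
       seed = as.integer(seed))
}

check_features <- function(features) {
  if (is.null(features)) features <- numeric(0)
  bad <- setdiff(names(features), feature_names())
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (any(abs(features) > 6))
    stop("feature deltas must lie within +/- 6 mm; got ",
         paste(sprintf("%s = %g", names(features)[abs(features) > 6],
                       features[abs(features) > 6]), collapse = ", "))
  features
}

# smooth random forward-displacement field on a coarse lattice; amplitude
# scaled to the requested RMS and clamped so the lattice gradient stays
# below max_grad (keeps the warp diffeomorphic)
random_smooth_field <- function(grid_size, spacing = 4, fwhm_mm = 12,
                                rms_mm = 1.5, max_grad = 0.3) {
  half <- (grid_size - 1) / 2
  nn <- length(seq(-half - 2, half + 2, by = spacing))
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -half - 2
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing
  disp <- array(0, dim = c(nn, nn, nn, 3))
  for (c in 1:3)
    disp[, , , c] <- array(cpp_gaussian_blur(rnorm(nn^3), rep(nn, 3L),
                                             rep(sigma_vox, 3)), dim = rep(nn, 3))
  rms <- sqrt(mean(disp^2) * 3)
  if (rms > 0) disp <- disp * (rms_mm / rms)
  gmax <- 0
  for (c in 1:3) for (ax in 1:3) {
    d <- dim(disp)[1:3]
    i1 <- slice_index(d, ax, -1); i2 <- slice_index(d, ax, +1)
    gmax <- max(gmax, max(abs(disp[i2$x, i2$y, i2$z, c] -
                              disp[i1$x, i1$y, i1$z, c])) / spacing)
  }
  if (gmax > max_grad) disp <- disp * (max_grad / gmax)
  cranio_field(disp, affine = aff)
}

# forward displacement (features + optional random field) at points
forward_displacement <- function(points, features, rand_field = NULL) {
  u <- feature_displacement(points, features)
  if (!is.null(rand_field)) u <- u + eval_field(rand_field, points)$disp
  u
}

# pull-back field reproducing a subject from the template:
#   subject(y) = template(psi(A^{-1} y)),  psi = (id + u_fwd)^{-1}
make_pullback <- function(geom, features, rand_field = NULL, scale = 1,
                          lattice_spacing = 2) {
  lat <- zero_field(geom, lattice_spacing)
  ldim <- dim(lat$disp)[1:3]
  idx <- as.matrix(expand.grid(x = seq_len(ldim[1]) - 1,
                               y = seq_len(ldim[2]) - 1,
                               z = seq_len(ldim[3]) - 1))
  nw <- t((lat$affine %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
  fwd <- cranio_field(array(forward_displacement(nw, features, rand_field),
                            dim = c(ldim, 3)), affine = lat$affine)
  psi <- invert_field(fwd, tol_mm = 0.005, max_iter = 50L)
  if (scale == 1) {
    # resample psi onto the volume lattice for direct use in resample()
    compose_transforms(psi, affine_transform(), lattice = geom)
  } else {
    a_inv <- affine_from_matrix(diag(c(1 / scale, 1 / scale, 1 / scale, 1)))
    compose_transforms(psi, a_inv, lattice = geom)
  }
}

#' @rdname synthetic_data
#' @param spec A [phantom_spec()].
#' @return `generate_phantom()` returns a list: `volume` (the noisy phantom),
#'   `landmarks` (true landmark positions, exact under the planted feature
#'   deltas), `field` (the true pull-back deformation from the canonical
#'   template, usable directly in [resample()]), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  tmpl <- canonical_template(spec$grid_size)
  geom <- geometry(tmpl)
  lms <- face_template_landmarks()
  deltas <- spec$features
  pure <- length(deltas) == 0 || all(deltas == 0)
  with_seed(spec$seed, {
    if (pure) {
      vol <- tmpl
      field <- compose_transforms(affine_transform(), affine_transform(),
                                  lattice = geom)
      lm_true <- lms
    } else {
      field <- make_pullback(geom, deltas)
      vol <- resample(tmpl, field, geom)
      lm_true <- landmark_set(lms$names,
                              lms$points + feature_displacement(lms$points, deltas),
                              space = "model")
    }
    dat <- vol$data
    if (spec$bias_field) {
      half <- (spec$grid_size - 1) / 2
      co <- seq(-half, half, by = 1)
      g <- expand.grid(x = co, y = co, z = co)
      dat <- dat * array(1 + 0.15 * (g$x + g$y + g$z) / (3 * half),
                         dim = dim(dat))
    }
    if (spec$noise_sd > 0)
      dat <- dat + array(rnorm(length(dat), 0, spec$noise_sd), dim = dim(dat))
    list(volume = cranio_volume(dat, vol$affine), landmarks = lm_true,
         field = field, spec = spec)
  })
}

#' Cohort specification with planted sex, age and body-fat effects
#'
#' Defines the population the synthetic cohort emulates: adolescents aged
#' 12-18 years (ages uniform over `age_range_months`, sex Bernoulli(1/2)),
#' facial-feature effects expressed in mm with the female-positive sign
#' convention (a positive `sex_effect` entry means the feature is larger in
#' females), optionally sex-specific age slopes in mm/month, log-normal
#' head-size scaling, a smooth random warp per subject, and a body-fat
#' percentage correlated with sex and (optionally) one facial feature so
#' body-fat residualisation can be exercised. Defaults plant the sexual
#' dimorphism pattern typical of adolescent faces: broader male jaw, chin,
#' mouth and nose; fuller female lips; male-dominant age slopes.
#'
#' @param n_subjects Cohort size (>= 3).
#' @param sex_effect Named feature deltas (mm), female-positive.
#' @param age_slope_male,age_slope_female Named feature slopes (mm/month),
#'   applied to age centred on the middle of `age_range_months`.
#' @param age_range_months Uniform age range (months).
#' @param headsize_sd SD of log head-size scale (0.03 is about a 3% linear
#'   size SD).
#' @param deformation_sd RMS amplitude (mm) of the smooth random warp.
#' @param warp_fwhm_mm Smoothness of the random warp.
#' @param noise_sd Intensity noise SD.
#' @param bodyfat_mean,bodyfat_sd,bodyfat_sex_delta Body-fat model: mean,
#'   residual SD and female-male difference (percentage points).
#' @param bodyfat_feature,bodyfat_feature_coef Feature whose per-subject
#'   delta leaks into body fat (percentage points per mm), creating the
#'   collinearity that residualisation is meant to absorb.
#' @param zero_mean_warps Centre the random warps across the cohort (useful
#'   for atlas-fidelity experiments where the population mean should equal
#'   the template).
#' @param headsize_scales Optional explicit per-subject linear scale factors
#'   (length `n_subjects`), overriding the log-normal draw - e.g. a cohort
#'   differing only by scales for head-size recovery experiments.
#' @param grid_size,seed As in [phantom_spec()].
#' @return A validated cohort spec list.
#' @export
cohort_spec <- function(n_subjects = 8,
                        sex_effect = c(nose_width = -2, jaw_width = -4,
                                       chin_protrusion = -2.5, mouth_width = -3,
                                       lip_fullness = 1.5, nose_length = -1.5),
                        age_slope_male = c(jaw_width = 0.05, chin_protrusion = 0.03,
                                           nose_length = 0.02, mouth_width = 0.03),
                        age_slope_female = c(mouth_width = 0.01, nose_length = 0.01),
                        age_range_months = c(144, 216),
                        headsize_sd = 0.03, deformation_sd = 1.5,
                        warp_fwhm_mm = 12, noise_sd = 3,
                        bodyfat_mean = 21, bodyfat_sd = 4, bodyfat_sex_delta = 6,
                        bodyfat_feature = "lip_fullness", bodyfat_feature_coef = 1,
                        zero_mean_warps = FALSE, headsize_scales = NULL,
                        grid_size = 64, seed = 1L) {
  stopifnot(n_subjects >= 3, headsize_sd >= 0, deformation_sd >= 0,
            noise_sd >= 0, length(age_range_months) == 2,
            age_range_months[2] > age_range_months[1])
  check_features(sex_effect); check_features(age_slope_male)
  check_features(age_slope_female)
  if (!is.null(bodyfat_feature) && !bodyfat_feature %in% feature_names())
    stop("unknown bodyfat_feature: ", bodyfat_feature)
  if (!is.null(headsize_scales)) {
    stopifnot(length(headsize_scales) == n_subjects, all(headsize_scales > 0))
  }
  as.list(environment())
}

# per-subject covariates and feature deltas (shared by the volume and
# landmark-level generators; call under with_seed)
draw_cohort_effects <- function(spec) {
  n <- spec$n_subjects
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  age <- runif(n, spec$age_range_months[1], spec$age_range_months[2])
  agec <- age - mean(spec$age_range_months)
  scale <- if (!is.null(spec$headsize_scales)) as.numeric(spec$headsize_scales)
           else exp(rnorm(n, 0, spec$headsize_sd))
  feats <- lapply(seq_len(n), function(i) {
    d <- setNames(numeric(length(feature_names())), feature_names())
    sc <- if (sex[i] == "female") 0.5 else -0.5
    d[names(spec$sex_effect)] <- d[names(spec$sex_effect)] + spec$sex_effect * sc
    sl <- if (sex[i] == "male") spec$age_slope_male else spec$age_slope_female
    if (length(sl)) d[names(sl)] <- d[names(sl)] + sl * agec[i]
    check_features(d)
  })
  bodyfat <- spec$bodyfat_mean +
    spec$bodyfat_sex_delta * (sex_code(sex) + 0.5) +
    (if (!is.null(spec$bodyfat_feature))
       spec$bodyfat_feature_coef *
         vapply(feats, function(d) d[[spec$bodyfat_feature]], numeric(1))
     else 0) +
    rnorm(n, 0, spec$bodyfat_sd)
  list(covariates = data.frame(subject = sprintf("s%02d", seq_len(n)),
                               sex = sex, age_months = age,
                               bodyfat_pct = bodyfat),
       features = feats, scale = scale)
}

#' @rdname cohort_spec
#' @param spec A [cohort_spec()].
#' @param verbose Print per-subject progress.
#' @return `generate_cohort()` returns `volumes` (named list of
#'   [cranio_volume]), `covariates` (data.frame: subject, sex, age_months,
#'   bodyfat_pct) and `truth`: the canonical template, the model-space
#'   landmark template, per-subject true pull-back fields, native- and
#'   linear-space landmark sets, feature deltas and head-size scales
#'   (`headsize_true` = scale^3).
#' @export
generate_cohort <- function(spec = cohort_spec(), verbose = FALSE) {
  tmpl <- canonical_template(spec$grid_size)
  geom <- geometry(tmpl)
  lms <- face_template_landmarks()
  with_seed(spec$seed, {
    eff <- draw_cohort_effects(spec)
    n <- spec$n_subjects
    rand <- vector("list", n)
    if (spec$deformation_sd > 0) {
      for (i in seq_len(n))
        rand[[i]] <- random_smooth_field(spec$grid_size, fwhm_mm = spec$warp_fwhm_mm,
                                         rms_mm = spec$deformation_sd)
      if (isTRUE(spec$zero_mean_warps)) {
        mean_disp <- Reduce(`+`, lapply(rand, `[[`, "disp")) / n
        for (i in seq_len(n))
          rand[[i]] <- cranio_field(rand[[i]]$disp - mean_disp, rand[[i]]$affine)
      }
    }
    volumes <- vector("list", n)
    subj_truth <- vector("list", n)
    for (i in seq_len(n)) {
      if (verbose) message("subject ", i, "/", n)
      field <- make_pullback(geom, eff$features[[i]], rand[[i]], eff$scale[i])
      vol <- resample(tmpl, field, geom)
      dat <- vol$data
      if (spec$noise_sd > 0)
        dat <- dat + array(rnorm(length(dat), 0, spec$noise_sd), dim = dim(dat))
      volumes[[i]] <- cranio_volume(dat, vol$affine)
      u_lin <- forward_displacement(lms$points, eff$features[[i]], rand[[i]])
      lm_linear <- landmark_set(lms$names, lms$points + u_lin, "subject_linear")
      lm_native <- landmark_set(lms$names, (lms$points + u_lin) * eff$scale[i],
                                "subject_linear")
      subj_truth[[i]] <- list(field = field, landmarks_linear = lm_linear,
                              landmarks_native = lm_native,
                              features = eff$features[[i]], scale = eff$scale[i])
    }
    names(volumes) <- eff$covariates$subject
    names(subj_truth) <- eff$covariates$subject
    list(volumes = volumes, covariates = eff$covariates,
         truth = list(template = tmpl, landmarks_model = lms,
                      subjects = subj_truth,
                      headsize_true = setNames(eff$scale^3, eff$covariates$subject)))
  })
}

#' Landmark-level cohort generator
#'
#' The cheap counterpart of [generate_cohort()] for statistical calibration
#' work: per-subject landmark sets in head-size-free `subject_linear` space
#' are produced directly (planted feature displacements + smooth random warp
#' evaluated at the landmarks + independent placement jitter), skipping
#' volume synthesis and registration entirely.
#'
#' @param spec A [cohort_spec()].
#' @param jitter_mm SD of independent per-coordinate landmark jitter,
#'   emulating residual registration/propagation error.
#' @return List with `landmark_sets` (named list of `cranio_landmarks`),
#'   `covariates` and `truth` (feature deltas per subject).
#' @export
generate_landmark_cohort <- function(spec = cohort_spec(), jitter_mm = 0.8) {
  lms <- face_template_landmarks()
  with_seed(spec$seed, {
    eff <- draw_cohort_effects(spec)
    n <- spec$n_subjects
    sets <- vector("list", n)
    for (i in seq_len(n)) {
      rf <- if (spec$deformation_sd > 0)
        random_smooth_field(spec$grid_size, fwhm_mm = spec$warp_fwhm_mm,
                            rms_mm = spec$deformation_sd) else NULL
      u <- forward_displacement(lms$points, eff$features[[i]], rf)
      pts <- lms$points + u + matrix(rnorm(3 * length(lms$names), 0, jitter_mm),
                                     ncol = 3)
      sets[[i]] <- landmark_set(lms$names, pts, "subject_linear")
    }
    names(sets) <- eff$covariates$subject
    list(landmark_sets = sets, covariates = eff$covariates,
         truth = list(features = eff$features, landmarks_model = lms))
  })
}
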