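#' Intensity-driven linear registration (6 / 9 / 12 parameters)
#'
#' Recovers the affine map that best aligns `source` to `target` by
#' maximising the normalised cross-correlation (NCC) of intensities over a
#' coarse-to-fine Gaussian blur pyramid, using derivative-free Nelder-Mead
#' optimisation of the transform parameters. Rotations and scalings are
#' taken about the centroid of the target head so the parameters stay well
#' conditioned regardless of where the world origin sits.
#'
#' The returned transform follows the pull-back convention of [resample()]:
#' it maps target world coordinates to source world coordinates, so
#' `resample(source, fit, geometry(target))` is the aligned source. If the
#' source was synthesised as `resample(template, A)`, registering it back to
#' the template recovers `A^{-1}`.
#'
#' @param source,target [cranio_volume] objects overlapping in world space.
#' @param dof Degrees of freedom: 6 (rigid), 9 (+ scales) or 12 (+ shears).
#' @param init Optional initial `cranio_affine` (pull-back). Default:
#'   identity rotation with a translation aligning intensity centroids.
#' @param pyramid_fwhm_mm Blur FWHMs of the pyramid, coarse to fine.
#' @param max_eval Nelder-Mead evaluation budget per pyramid level.
#' @return A [cranio_affine]; attribute `ncc` holds the final similarity.
#'   If the optimiser failed to improve on the initialisation, attribute
#'   `converged` is `FALSE` and a warning is attached (never an error).
#' @export
register_linear <- function(source, target, dof = 9, init = NULL,
                            pyramid_fwhm_mm = c(8, 4, 2),
                            max_eval = c(400, 250, 150)) {
  stopifnot(is_volume(source), is_volume(target))
  if (!dof %in% c(6, 9, 12)) stop("dof must be 6, 9 or 12")
  max_eval <- rep_len(max_eval, length(pyramid_fwhm_mm))

  centre <- head_centroid(target)
  Tc <- diag(4); Tc[1:3, 4] <- centre
  Tci <- diag(4); Tci[1:3, 4] <- -centre

  # parameter vector: rx ry rz tx ty tz [log s1 s2 s3] [h1 h2 h3]
  npar <- c(`6` = 6L, `9` = 9L, `12` = 12L)[[as.character(dof)]]
  par2mat <- function(p) {
    p <- c(p, rep(0, 12 - length(p)))
    m <- affine_transform(rotations = p[1:3], translations = p[4:6],
                          scales = exp(p[7:9]), shears = p[10:12])$matrix
    Tc %*% m %*% Tci
  }

  p0 <- rep(0, npar)
  if (is.null(init)) {
    p0[4:6] <- head_centroid(source) - centre
  } else {
    # express init about the registration centre
    m0 <- Tci %*% init$matrix %*% Tc
    d0 <- decompose_affine(m0)
    p0[1:3] <- d0$rotations; p0[4:6] <- d0$translations
    if (npar >= 9) p0[7:9] <- log(d0$scales)
    if (npar >= 12) p0[10:12] <- d0$shears
  }

  src_dat <- as.numeric(source$data); sdim <- as.integer(dim(source$data))
  tdim <- as.integer(dim(target$data))
  src_inv <- solve(source$affine)
  # similarity is evaluated over the (dilated) target head: background voxels
  # carry no alignment information and would dilute the correlation
  tmask <- gaussian_blur(cranio_volume(head_mask(target) * 1, target$affine), 4)
  tmask <- as.integer(tmask$data > 0.05)
  objective <- function(p, tgt_dat) {
    vm <- src_inv %*% par2mat(p) %*% target$affine
    -cpp_ncc_affine(src_dat, sdim, tgt_dat, tdim, vm, tmask)
  }

  parscale <- c(rep(0.02, 3), rep(2, 3), rep(0.02, 3), rep(0.02, 3))[1:npar]
  p <- p0
  tmask_full <- tmask
  for (lev in seq_along(pyramid_fwhm_mm)) {
    f <- pyramid_fwhm_mm[lev]
    tgt_b <- as.numeric(gaussian_blur(target, f)$data)
    src_b <- gaussian_blur(source, f)
    src_dat <- as.numeric(src_b$data) # closure uses src_dat
    # at heavily blurred levels the image is oversampled: evaluating the
    # similarity on a strided subset of the head voxels loses nothing
    stride <- max(1L, as.integer(round(f / min(voxel_size(target)) / 4)))
    tmask <- tmask_full
    if (stride > 1L) {
      keep <- array(FALSE, dim = dim(target$data))
      keep[seq(1, dim(keep)[1], stride), seq(1, dim(keep)[2], stride),
           seq(1, dim(keep)[3], stride)] <- TRUE
      tmask <- as.integer(tmask_full & as.integer(keep))
    }
    # restarted Nelder-Mead: a fresh simplex around the current optimum
    # escapes the degenerate simplices the method is prone to in 9-12
    # dimensions
    for (restart in 1:2) {
      fit <- optim(p, objective, tgt_dat = tgt_b, method = "Nelder-Mead",
                   control = list(maxit = max_eval[lev], parscale = parscale,
                                  reltol = 1e-10))
      p <- fit$par
    }
  }
  src_dat <- as.numeric(source$data)
  ncc_final <- -objective(p, as.numeric(target$data))
  ncc_init <- -objective(p0, as.numeric(target$data))
  out <- affine_from_matrix(par2mat(p))
  attr(out, "ncc") <- ncc_final
  attr(out, "converged") <- ncc_final >= ncc_init - 1e-9
  if (!attr(out, "converged"))
    warning("linear registration did not improve similarity over its initialisation")
  out
}

head_centroid <- function(volume) {
  m <- head_mask(volume)
  idx <- which(m, arr.ind = TRUE) - 1
  if (nrow(idx) == 0) idx <- matrix((dim(volume$data) - 1) / 2, ncol = 3)
  colMeans(voxel_to_world(volume, idx))
}

#' Registration schedules and optimiser settings
#'
#' `nonlinear_schedule()` validates an ordered multi-resolution schedule:
#' node step sizes (mm), iteration counts and image blur FWHMs (mm), with
#' steps and blurs non-increasing. `full_schedule()` returns the default
#' schedule used for 1-mm human head data (steps 8, 8, 4, 4, 2, 2 mm;
#' 30/30/30/30/10/10 iterations; blurs 16, 8, 8, 4, 4, 2 mm).
#' `phantom_schedule()` is the scaled variant for the 64 mm synthetic
#' phantoms (steps 8, 4, 2 mm at 10/10/5 iterations, blurs 8, 4, 2 mm).
#'
#' @param step_mm,iterations,blur_fwhm_mm Equal-length numeric vectors.
#' @return A data.frame of class `cranio_schedule`.
#' @export
nonlinear_schedule <- function(step_mm, iterations, blur_fwhm_mm) {
  if (length(step_mm) == 0) stop("schedule must contain at least one step")
  stopifnot(length(step_mm) == length(iterations),
            length(step_mm) == length(blur_fwhm_mm))
  if (any(step_mm <= 0) || any(blur_fwhm_mm <= 0) || any(iterations <= 0))
    stop("schedule entries must be positive")
  if (any(diff(step_mm) > 0)) stop("step sizes must be non-increasing")
  if (any(diff(blur_fwhm_mm) > 0)) stop("blur FWHMs must be non-increasing")
  structure(data.frame(step_mm = step_mm, iterations = as.integer(iterations),
                       blur_fwhm_mm = blur_fwhm_mm),
            class = c("cranio_schedule", "data.frame"))
}

#' @rdname nonlinear_schedule
#' @export
full_schedule <- function() {
  nonlinear_schedule(step_mm = c(8, 8, 4, 4, 2, 2),
                     iterations = c(30, 30, 30, 30, 10, 10),
                     blur_fwhm_mm = c(16, 8, 8, 4, 4, 2))
}

#' @rdname nonlinear_schedule
#' @export
phantom_schedule <- function() {
  nonlinear_schedule(step_mm = c(8, 4, 2), iterations = c(10, 10, 5),
                     blur_fwhm_mm = c(8, 4, 2))
}

#' @rdname nonlinear_schedule
#' @param stiffness,weight,similarity Regularisation knobs: each node update
#'   blends the data-driven move with the Gaussian-smoothed neighbourhood
#'   field using `alpha = similarity / (similarity + stiffness * weight)`.
#' @param search_radius_factor Spherical search radius around each node, in
#'   multiples of the step size.
#' @return `optimizer_config` returns a list of optimiser settings.
#' @export
optimizer_config <- function(stiffness = 1, weight = 1, similarity = 0.3,
                             search_radius_factor = 3) {
  stopifnot(stiffness > 0, weight > 0, similarity > 0, search_radius_factor > 0)
  list(stiffness = stiffness, weight = weight, similarity = similarity,
       search_radius_factor = search_radius_factor)
}

#' Multi-resolution nonlinear registration by local block matching
#'
#' Estimates a dense displacement field aligning `source` to `target`
#' (already linearly registered). For each schedule step both images are
#' blurred at the stated FWHM and control nodes are placed on a lattice at
#' the step spacing; each node's local translation is optimised by
#' Nelder-Mead simplex search (initial edge `step/2`, at most `max_eval`
#' evaluations) of the local NCC over a spherical intensity window of radius
#' equal to the step size, within a search sphere of radius
#' `search_radius_factor * step`. Data-driven updates are blended with the
#' Gaussian-smoothed neighbourhood field (sigma = one node spacing):
#' `u <- alpha * u_data + (1 - alpha) * smooth(u)`, where
#' `alpha = similarity / (similarity + stiffness * weight)`. Nodes over flat
#' (background) target regions take the smoothed field only. Each step's
#' field initialises the next, finer step.
#'
#' @param source,target [cranio_volume] objects on compatible world frames.
#' @param schedule A [nonlinear_schedule()].
#' @param config An [optimizer_config()].
#' @param init Optional initial [cranio_field] (pull-back, target to source).
#' @param mask Optional logical array on the target grid limiting the nodes
#'   optimised; defaults to a dilated head mask of the target.
#' @param max_eval Simplex evaluation budget per node.
#' @return A [cranio_field] mapping target points to source points, defined
#'   on the node lattice of the finest step. Attributes `ncc` and `ncc_init`
#'   trace the masked source-target NCC after and before each schedule step,
#'   measured at that step's blur level.
#' @export
register_nonlinear <- function(source, target, schedule = phantom_schedule(),
                               config = optimizer_config(), init = NULL,
                               mask = NULL, max_eval = 50L) {
  stopifnot(is_volume(source), is_volume(target))
  if (!inherits(schedule, "cranio_schedule")) stop("schedule must be a cranio_schedule")
  alpha <- config$similarity / (config$similarity + config$stiffness * config$weight)
  if (is.null(mask)) {
    mk <- gaussian_blur(cranio_volume(head_mask(target) * 1, target$affine), 6)
    mask <- mk$data > 0.05
  }
  field <- init
  ncc_trace <- numeric(0)
  ncc_init_trace <- numeric(0)
  for (s in seq_len(nrow(schedule))) {
    step <- schedule$step_mm[s]
    blur <- schedule$blur_fwhm_mm[s]
    src_b <- gaussian_blur(source, blur)
    tgt_b <- gaussian_blur(target, blur)
    new_lattice <- zero_field(target, step)
    ndim <- dim(new_lattice$disp)[1:3]
    # node world coordinates and initial displacements
    idx <- as.matrix(expand.grid(x = seq_len(ndim[1]) - 1,
                                 y = seq_len(ndim[2]) - 1,
                                 z = seq_len(ndim[3]) - 1))
    nw <- t((new_lattice$affine %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
    if (is.null(field)) {
      disp <- matrix(0, nrow(nw), 3)
    } else {
      disp <- eval_field(field, nw)$disp
    }
    # node activity from the target mask
    nv <- world_to_voxel(target, nw)
    nvr <- pmin(pmax(round(nv), 0), matrix(rep(dim(target$data) - 1, each = nrow(nv)), ncol = 3))
    lin <- 1 + nvr[, 1] + dim(target$data)[1] * (nvr[, 2] + dim(target$data)[2] * nvr[, 3])
    node_in_mask <- as.logical(mask[lin])
    offsets <- sphere_offsets(radius = step, spacing = max(min(voxel_size(target)), step / 2))
    tgt_sd <- sd(tgt_b$data[mask])
    step_ncc <- function(fld) {
      warped <- if (is.null(fld)) resample(source, NULL, geometry(target))
                else resample(source, fld, geometry(target))
      volume_ncc(gaussian_blur(warped, blur), tgt_b, mask = mask)
    }
    ncc0 <- step_ncc(field)
    ncc_init_trace <- c(ncc_init_trace, ncc0)
    disp0 <- disp
    for (it in seq_len(schedule$iterations[s])) {
      upd <- cpp_node_updates(as.numeric(src_b$data), as.integer(dim(src_b$data)),
                              solve(src_b$affine),
                              as.numeric(tgt_b$data), as.integer(dim(tgt_b$data)),
                              solve(tgt_b$affine),
                              nw, disp, offsets,
                              search_radius = config$search_radius_factor * step,
                              simplex_edge = step / 2,
                              max_eval = as.integer(max_eval),
                              min_tsd = 0.02 * tgt_sd)
      active <- upd$active == 1L & node_in_mask
      prop <- upd$proposal
      # regularised update: the data-driven increment, damped by alpha, is
      # smoothed over the node lattice (weighted by node activity so flat
      # regions take the consensus of their informative neighbours); nodes
      # without usable intensity then relax to the smoothed field itself.
      # Smoothing the increment instead of the accumulated field keeps the
      # equilibrium unbiased: where the data are consistent, the field
      # converges to the data optimum at full amplitude.
      inc <- matrix(0, nrow(prop), 3)
      inc[active, ] <- alpha * (prop[active, ] - disp[active, ])
      disp <- disp + smooth_weighted_field(inc, active * 1, ndim, sigma_nodes = 1)
      smoothed <- smooth_node_field(disp, ndim, sigma_nodes = 1)
      disp[!active, ] <- smoothed[!active, ]
    }
    field <- cranio_field(array(disp, dim = c(ndim, 3)), affine = new_lattice$affine)
    ncc1 <- step_ncc(field)
    if (ncc1 < ncc0) {
      # refinement failed to improve the step's similarity (typically at the
      # finest level, where changes sit at the noise floor): reject it and
      # carry the incoming field forward on the new lattice
      field <- cranio_field(array(disp0, dim = c(ndim, 3)), affine = new_lattice$affine)
      ncc1 <- step_ncc(field)
    }
    ncc_trace <- c(ncc_trace, ncc1)
  }
  # per-step similarity at that step's own blur, before and after its
  # iterations: each step should not degrade the objective it optimises
  attr(field, "ncc") <- ncc_trace
  attr(field, "ncc_init") <- ncc_init_trace
  field
}

# world-mm offsets sampling a sphere; always includes the centre point
sphere_offsets <- function(radius, spacing) {
  r <- seq(-radius, radius, by = spacing)
  g <- as.matrix(expand.grid(x = r, y = r, z = r))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

# weight-normalised Gaussian smoothing: average of nearby values with the
# given per-node weights (e.g. node activity), extended smoothly into
# zero-weight regions
smooth_weighted_field <- function(disp, weights, ndim, sigma_nodes = 1) {
  wb <- cpp_gaussian_blur(weights, as.integer(ndim), rep(sigma_nodes, 3))
  out <- disp
  for (c in 1:3) {
    b <- cpp_gaussian_blur(disp[, c] * weights, as.integer(ndim), rep(sigma_nodes, 3))
    out[, c] <- ifelse(wb > 1e-10, b / wb, 0)
  }
  out
}

# normalised Gaussian smoothing of an m x 3 node displacement matrix living
# on an ndim lattice (sigma in node units); zero-padding corrected by
# dividing by the blurred indicator so edge nodes are not shrunk
smooth_node_field <- function(disp, ndim, sigma_nodes = 1) {
  ones <- cpp_gaussian_blur(rep(1, prod(ndim)), as.integer(ndim), rep(sigma_nodes, 3))
  out <- disp
  for (c in 1:3) {
    b <- cpp_gaussian_blur(disp[, c], as.integer(ndim), rep(sigma_nodes, 3))
    out[, c] <- b / ones
  }
  out
}
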