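#' Jacobian determinant map of a displacement field
#'
#' Computes `det(I + grad(u))` at every voxel of the requested geometry,
#' where `u` is the world-mm displacement and the gradient is taken with
#' respect to world coordinates by central finite differences (one-sided at
#' the borders). Values above 1 indicate local volume expansion of the
#' subject relative to the template, values below 1 local contraction.
#'
#' @param field A [cranio_field] (pull-back, template space to subject).
#' @param target Geometry on which to evaluate (defaults to the field's own
#'   node lattice).
#' @return A [cranio_volume] of determinants. Non-positive determinants are
#'   permitted in the output; their count is available as attribute
#'   `n_nonpositive`.
#' @export
jacobian_map <- function(field, target = NULL) {
  stopifnot(is_field(field))
  if (is.null(target)) {
    disp <- field$disp
    aff <- field$affine
    ndim <- dim(disp)[1:3]
  } else {
    g <- geometry(target)
    ndim <- g$dim
    aff <- g$affine
    idx <- as.matrix(expand.grid(x = seq_len(ndim[1]) - 1,
                                 y = seq_len(ndim[2]) - 1,
                                 z = seq_len(ndim[3]) - 1))
    pts <- t((aff %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
    disp <- array(eval_field(field, pts)$disp, dim = c(ndim, 3))
  }
  jac <- cpp_jacobian(as.numeric(disp), as.integer(ndim), solve(aff[1:3, 1:3]))
  out <- cranio_volume(array(jac, dim = ndim), affine = aff)
  attr(out, "n_nonpositive") <- sum(jac <= 0)
  out
}

#' Face-region search mask
#'
#' Restricts voxel-wise analysis to the face: head voxels (intensity above a
#' background threshold) anterior to a coronal plane at the top of the
#' forehead, excluding everything posterior to it. Anterior is +y in the
#' package's RAS world convention.
#'
#' @param model Atlas [cranio_volume].
#' @param forehead_plane_y World y coordinate (mm) of the cutting plane;
#'   voxels with y >= this value are retained.
#' @param intensity_frac Background threshold as a fraction of the robust
#'   maximum intensity.
#' @return A [cranio_volume] with 0/1 data.
#' @export
make_face_mask <- function(model, forehead_plane_y, intensity_frac = 0.15) {
  stopifnot(is_volume(model))
  d <- dim(model$data)
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  yw <- (model$affine %*% rbind(t(idx), 1))[2, ]
  rng <- range(yw)
  if (forehead_plane_y < rng[1] || forehead_plane_y > rng[2])
    stop("forehead plane y = ", forehead_plane_y,
         " mm is outside the model field of view [",
         sprintf("%.1f, %.1f", rng[1], rng[2]), "]")
  mask <- head_mask(model, frac = intensity_frac) & array(yw >= forehead_plane_y, dim = d)
  if (!any(mask))
    stop("face mask is empty: the forehead plane excludes the entire head")
  cranio_volume(mask * 1, affine = model$affine)
}

#' Voxel-wise general linear model on Jacobian maps
#'
#' Fits an ordinary-least-squares GLM at every in-mask voxel of the (blurred)
#' Jacobian maps and returns the t statistic of a contrast:
#' `t = c'beta / sqrt(c' (X'X)^-1 c * sigma2)`, with `df = n - rank(X)`.
#' By convention sex should be coded so that positive coefficients mean
#' larger values in females (see [sex_code()]).
#'
#' @param jacobians List of per-subject [cranio_volume] Jacobian maps on a
#'   common grid (typically blurred at 8 mm FWHM).
#' @param design Numeric design matrix (n subjects x p regressors) including
#'   an intercept column.
#' @param contrast Numeric contrast vector of length p.
#' @param mask [cranio_volume] or logical array restricting the analysis.
#' @param fwhm_mm Smoothness to record if residual-based estimation is not
#'   possible (fewer than 10 subjects); defaults to the blur applied.
#' @return An object of class `cranio_statmap`: `t` ([cranio_volume], 0
#'   outside the mask), `df`, `mask`, `fwhm_est_mm`, `design_labels`,
#'   `effect` (contrast estimate volume) and `residual_sd`.
#' @export
fit_glm <- function(jacobians, design, contrast, mask, fwhm_mm = 8) {
  stopifnot(is.list(jacobians), length(jacobians) >= 3)
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (length(jacobians) != n)
    stop("number of Jacobian maps (", length(jacobians),
         ") does not match design rows (", n, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    labs <- colnames(X)[qx$pivot[seq(qx$rank + 1, p)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(labs, collapse = ", "))
  }
  if (length(contrast) != p) stop("contrast length must equal the number of regressors")
  mk <- if (is_volume(mask)) mask$data != 0 else mask != 0
  keep <- as.logical(mk)
  Y <- vapply(jacobians, function(v) as.numeric(v$data)[keep], numeric(sum(keep)))
  Y <- t(Y) # n x V
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- n - qx$rank
  sigma2 <- colSums(res^2) / df
  cvec <- as.numeric(contrast)
  se <- sqrt(as.numeric(t(cvec) %*% XtXinv %*% cvec) * sigma2)
  eff <- as.numeric(t(cvec) %*% beta)
  tval <- ifelse(se > 0, eff / se, 0)

  fwhm_est <- if (n >= 10) {
    tryCatch(estimate_smoothness(res, mk, geom = geometry(jacobians[[1]])),
             error = function(e) fwhm_mm)
  } else fwhm_mm

  d <- dim(mk)
  tvol <- array(0, dim = d); tvol[keep] <- tval
  evol <- array(0, dim = d); evol[keep] <- eff
  structure(list(t = cranio_volume(tvol, jacobians[[1]]$affine),
                 effect = cranio_volume(evol, jacobians[[1]]$affine),
                 df = df,
                 mask = cranio_volume(mk * 1, jacobians[[1]]$affine),
                 fwhm_est_mm = fwhm_est,
                 design_labels = colnames(X),
                 residual_sd = sqrt(sigma2)),
            class = "cranio_statmap")
}

#' @export
print.cranio_statmap <- function(x, ...) {
  tv <- x$t$data[x$mask$data != 0]
  cat(sprintf("<cranio_statmap> df = %d, %d in-mask voxels, t range [%.2f, %.2f], FWHM %.2f mm\n",
              x$df, length(tv), min(tv), max(tv), x$fwhm_est_mm))
  invisible(x)
}

#' Sex coding with the female-positive convention
#'
#' Centred +/- 1/2 coding: females +0.5, males -0.5, so that coefficients
#' greater than 0 indicate greater values in females and the interaction
#' terms stay interpretable.
#' @param sex Character/factor vector with values "F"/"female" or "M"/"male".
#' @return Numeric vector in {-0.5, +0.5}.
#' @export
sex_code <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("f", "female"), 0.5,
                ifelse(s %in% c("m", "male"), -0.5, NA_real_))
  if (any(is.na(out))) stop("sex values must be male/female (or M/F)")
  out
}

#' Estimate residual field smoothness (FWHM)
#'
#' Standard resel estimation: residual maps are normalised voxel-wise to unit
#' sum of squares, per-axis derivative variances are pooled over voxels and
#' subjects, and each axis FWHM is `sqrt(4 log 2 / lambda_axis)`. The global
#' value is the geometric mean of the per-axis FWHMs.
#'
#' @param residuals n x V matrix of in-mask residuals (or list of residual
#'   [cranio_volume]s, in which case `mask` selects the voxels).
#' @param mask Logical array (required to re-embed matrix input).
#' @param geom Geometry of the residual volumes (for the voxel size).
#' @return Scalar FWHM in mm; attribute `per_axis` carries the axis values.
#' @export
estimate_smoothness <- function(residuals, mask, geom) {
  mk <- if (is_volume(mask)) mask$data != 0 else mask != 0
  if (!any(mk)) stop("empty mask")
  d <- dim(mk)
  vs <- sqrt(colSums(geom$affine[1:3, 1:3]^2))
  if (is.list(residuals))
    residuals <- t(vapply(residuals, function(v) as.numeric(v$data)[as.logical(mk)],
                          numeric(sum(mk))))
  n <- nrow(residuals)
  if (n < 10) stop("need at least 10 residual maps to estimate smoothness")
  ssq <- colSums(residuals^2)
  if (any(ssq == 0)) stop("constant residuals: zero gradient variance")
  R <- residuals / rep(sqrt(ssq), each = n)
  # re-embed and difference along each axis
  lam <- numeric(3)
  emb <- array(0, dim = c(d, n))
  keep <- which(as.logical(mk))
  for (i in seq_len(n)) {
    sl <- array(0, dim = d); sl[keep] <- R[i, ]
    emb[, , , i] <- sl
  }
  for (ax in 1:3) {
    idx1 <- slice_index(d, ax, -1); idx2 <- slice_index(d, ax, +1)
    diffs <- (emb[idx2$x, idx2$y, idx2$z, , drop = FALSE] -
              emb[idx1$x, idx1$y, idx1$z, , drop = FALSE]) / vs[ax]
    mk_pair <- mk[idx2$x, idx2$y, idx2$z, drop = FALSE] & mk[idx1$x, idx1$y, idx1$z, drop = FALSE]
    svox <- array(rowSums(matrix(diffs^2, ncol = n)), dim = dim(mk_pair))
    lam[ax] <- mean(svox[mk_pair])
  }
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("constant residuals: zero gradient variance")
  fwhm_axis <- sqrt(4 * log(2) / lam)
  out <- prod(fwhm_axis)^(1 / 3)
  attr(out, "per_axis") <- fwhm_axis
  out
}

slice_index <- function(d, axis, side) {
  ix <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  if (side < 0) ix[[axis]] <- ix[[axis]][-d[axis]] else ix[[axis]] <- ix[[axis]][-1]
  ix
}
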