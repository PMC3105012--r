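#' Thin-plate-spline warps between matched landmark sets
#'
#' Fits the 3D interpolating thin-plate spline with kernel `U(r) = r` (the
#' biharmonic Green's function in three dimensions) mapping each source
#' landmark exactly onto its target, with a full affine part. The spline
#' minimises bending energy among all interpolants; a globally affine
#' displacement is reproduced exactly with zero nonlinear weights.
#'
#' @param source,target `cranio_landmarks` with matching names; source points
#'   must be distinct.
#' @return An object of class `cranio_tps`: `source_points`, `affine` (4 x 3:
#'   rows are the constant and the x/y/z linear coefficients) and `weights`
#'   (n x 3 kernel coefficients).
#' @export
tps_fit <- function(source, target) {
  stopifnot(is_landmarks(source), is_landmarks(target))
  if (!setequal(source$names, target$names))
    stop("source and target landmark names must match")
  S <- source$points
  T_ <- target$points[source$names, , drop = FALSE]
  n <- nrow(S)
  D <- as.matrix(stats::dist(S))
  if (any(D[upper.tri(D)] < 1e-9))
    stop("duplicate source points make the TPS system singular")
  K <- D # U(r) = r
  P <- cbind(1, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(T_ - S, matrix(0, 4, 3)) # solve for the displacement
  sol <- solve(L, rhs)
  structure(list(source_points = S,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE],
                 names = source$names),
            class = "cranio_tps")
}

#' @rdname tps_fit
#' @param warp A `cranio_tps`.
#' @param points n x 3 matrix of world points (or a `cranio_landmarks`).
#' @return `tps_apply` returns the warped points (matrix, or landmark set if
#'   one was supplied).
#' @export
tps_apply <- function(warp, points) {
  stopifnot(inherits(warp, "cranio_tps"))
  as_lm <- is_landmarks(points)
  pts <- if (as_lm) points$points else matrix(as.numeric(points), ncol = 3)
  # displacement = P a + U w
  Pm <- cbind(1, pts)
  ## pairwise distances to source points
  d2 <- outer(rowSums(pts^2), rowSums(warp$source_points^2), `+`) -
    2 * pts %*% t(warp$source_points)
  U <- sqrt(pmax(d2, 0))
  disp <- Pm %*% warp$affine + U %*% warp$weights
  out <- pts + disp
  if (as_lm) landmark_set(points$names, out, space = points$space) else out
}

#' Bending energy of a thin-plate-spline warp
#'
#' The quadratic form `sum_c w_c' K w_c` over the three displacement
#' components; zero if and only if the displacement is globally affine.
#' @param warp A `cranio_tps`.
#' @return Non-negative scalar.
#' @export
tps_bending_energy <- function(warp) {
  K <- as.matrix(stats::dist(warp$source_points))
  -sum(vapply(1:3, function(c) {
    w <- warp$weights[, c]
    as.numeric(t(w) %*% K %*% w)
  }, numeric(1)))
}

#' Warp a volume with a thin-plate-spline
#'
#' Resamples `volume` through the inverse-free pull-back trick: the TPS
#' fitted from the *displaced* landmarks back to the originals is used as
#' the pull-back map, so the rendered volume shows the displaced face.
#' @param volume Atlas [cranio_volume].
#' @param warp_back A `cranio_tps` fitted from displaced to original
#'   landmarks (note the direction).
#' @param target Output geometry (defaults to the volume's own).
#' @return A warped [cranio_volume].
#' @export
tps_warp_volume <- function(volume, warp_back, target = NULL) {
  g <- geometry(if (is.null(target)) volume else target)
  idx <- as.matrix(expand.grid(x = seq_len(g$dim[1]) - 1,
                               y = seq_len(g$dim[2]) - 1,
                               z = seq_len(g$dim[3]) - 1))
  pts <- t((g$affine %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
  src_pts <- tps_apply(warp_back, pts)
  vox <- world_to_voxel(volume, src_pts)
  ## sample by building a temporary displacement-free affine resample path
  vals <- cpp_eval_volume_at(as.numeric(volume$data), as.integer(dim(volume$data)), vox)
  cranio_volume(array(vals, dim = g$dim), affine = g$affine)
}
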