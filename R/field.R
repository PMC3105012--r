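#' Dense displacement fields
#'
#' A deformation field stores world-mm displacement vectors on a regular
#' lattice (its *node grid*), with its own voxel-to-world affine. Fields
#' follow the same pull-back convention as [resample()]: a field attached to
#' a target geometry maps target world points `x` to source points
#' `x + u(x)`, with `u` evaluated by trilinear interpolation of the node
#' vectors (edge-clamped outside the lattice).
#'
#' @param disp 4D array `[nx, ny, nz, 3]` of displacements (mm, world frame).
#' @param affine 4x4 voxel-to-world matrix of the node lattice.
#' @return An object of class `cranio_field`.
#' @export
cranio_field <- function(disp, affine) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L)
    stop("disp must be an [nx, ny, nz, 3] array")
  if (!all(is.finite(disp))) stop("displacements must be finite")
  structure(list(disp = disp, affine = as.matrix(affine)), class = "cranio_field")
}

is_field <- function(x) inherits(x, "cranio_field")

#' @export
print.cranio_field <- function(x, ...) {
  d <- dim(x$disp)
  mags <- sqrt(rowSums(matrix(x$disp, ncol = 3)^2))
  cat(sprintf("<cranio_field> %d x %d x %d nodes, spacing %s mm, |u| max %.3f mm\n",
              d[1], d[2], d[3],
              paste(sprintf("%.3g", node_spacing(x)), collapse = " x "),
              max(mags)))
  invisible(x)
}

#' @rdname cranio_field
#' @param field A `cranio_field`.
#' @return `node_spacing` returns the per-axis lattice spacing in mm.
#' @export
node_spacing <- function(field) {
  sqrt(colSums(field$affine[1:3, 1:3]^2))
}

# zero field on a node lattice covering a geometry at a given spacing (mm)
zero_field <- function(target, spacing_mm) {
  g <- geometry(target)
  vs <- sqrt(colSums(g$affine[1:3, 1:3]^2))
  extent <- (g$dim - 1) * vs
  n <- pmax(2L, as.integer(floor(extent / spacing_mm)) + 1L)
  aff <- g$affine %*% diag(c(spacing_mm / vs, 1))
  cranio_field(array(0, dim = c(n, 3)), affine = aff)
}

#' Evaluate a displacement field at world points
#' @param field A [cranio_field].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return List with `disp` (n x 3 displacements, mm) and `inside` (logical;
#'   `FALSE` where the point fell outside the node lattice and the
#'   edge-clamped value was used).
#' @export
eval_field <- function(field, points) {
  stopifnot(is_field(field))
  pts <- matrix(as.numeric(points), ncol = 3)
  out <- cpp_eval_field(as.numeric(field$disp), as.integer(dim(field$disp)[1:3]),
                        solve(field$affine), pts)
  list(disp = out[, 1:3, drop = FALSE], inside = out[, 4] > 0.5)
}

#' Apply a transform to world points
#' @param transform A [cranio_affine] or [cranio_field].
#' @param points n x 3 matrix of world points.
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(transform, points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  if (is_affine(transform)) {
    t((transform$matrix %*% rbind(t(pts), 1))[1:3, , drop = FALSE])
  } else if (is_field(transform)) {
    pts + eval_field(transform, pts)$disp
  } else stop("transform must be a cranio_affine or cranio_field")
}

#' Compose two transforms into a displacement field
#'
#' Returns the field of the point map `x -> outer(inner(x))`, sampled on the
#' node lattice of `inner` when it is a field (otherwise of `outer`).
#' Affine-affine composition returns a [cranio_affine] instead.
#'
#' @param outer,inner [cranio_affine] or [cranio_field] objects, interpreted
#'   as point maps under the pull-back convention.
#' @param lattice Optional geometry or field providing the output lattice.
#' @return A [cranio_field] (or [cranio_affine] if both inputs are affine).
#' @export
compose_transforms <- function(outer, inner, lattice = NULL) {
  if (is_affine(outer) && is_affine(inner) && is.null(lattice))
    return(affine_from_matrix(outer$matrix %*% inner$matrix))
  lat <- if (!is.null(lattice)) lattice
         else if (is_field(inner)) inner
         else outer
  aff <- if (is_field(lat)) lat$affine else geometry(lat)$affine
  ldim <- if (is_field(lat)) dim(lat$disp)[1:3] else geometry(lat)$dim
  # node world coordinates
  idx <- as.matrix(expand.grid(x = seq_len(ldim[1]) - 1,
                               y = seq_len(ldim[2]) - 1,
                               z = seq_len(ldim[3]) - 1))
  pts <- t((aff %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
  mid <- transform_points(inner, pts)
  fin <- transform_points(outer, mid)
  cranio_field(array(fin - pts, dim = c(ldim, 3)), affine = aff)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(y) = -u(y + v(y))` at every node of the field lattice, so that
#' composing the field with its inverse is the identity up to `tol_mm`. The
#' input should be diffeomorphic (positive Jacobian determinant); a field
#' whose minimum Jacobian is negative is rejected.
#'
#' @param field A [cranio_field].
#' @param tol_mm Per-node convergence tolerance in mm.
#' @param max_iter Maximum fixed-point iterations per node.
#' @return The inverse [cranio_field]. If more than 1% of nodes fail to
#'   converge a warning reports the count (attribute `nonconv`).
#' @export
invert_field <- function(field, tol_mm = 0.05, max_iter = 20L) {
  stopifnot(is_field(field))
  jac <- cpp_jacobian(as.numeric(field$disp), as.integer(dim(field$disp)[1:3]),
                      solve(field$affine[1:3, 1:3]))
  if (min(jac) <= 0)
    stop("field is not invertible: minimum Jacobian determinant ",
         format(min(jac), digits = 4))
  res <- cpp_invert_field(as.numeric(field$disp), as.integer(dim(field$disp)[1:3]),
                          field$affine, solve(field$affine), tol_mm,
                          as.integer(max_iter))
  out <- cranio_field(array(res$disp, dim = dim(field$disp)), affine = field$affine)
  nn <- res$nonconv
  attr(out, "nonconv") <- nn
  if (nn > 0.01 * prod(dim(field$disp)[1:3]))
    warning(nn, " of ", prod(dim(field$disp)[1:3]),
            " nodes did not reach the inversion tolerance")
  out
}

#' Read / write displacement fields as 4D NIfTI plus a metadata sidecar
#'
#' The three displacement components (mm, world frame) are stored as the 4th
#' dimension; a small JSON sidecar (`<path>.json`) records the node spacing
#' and the pull-back direction convention.
#' @param field A [cranio_field].
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_field <- function(field, path) {
  stopifnot(is_field(field))
  img <- RNifti::asNifti(field$disp, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(node_spacing_mm = node_spacing(field),
                            convention = "pullback: maps target world point x to source point x + u(x)",
                            units = "mm"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D displacement field with 3 components: ", path)
  cranio_field(array(as.numeric(img), dim = d),
               affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}
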