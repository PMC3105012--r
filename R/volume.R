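#' @useDynLib craniomorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm optim pf pt qt quantile rnorm runif sd setNames
#'   uniroot var
#' @importFrom utils read.delim write.table
NULL

#' 3D scalar volume with a world coordinate map
#'
#' The basic image container of the package: a 3D numeric array together with
#' a 4x4 voxel-to-world affine (NIfTI convention, 0-based voxel indices,
#' world units mm, right-handed RAS orientation: +x right, +y anterior,
#' +z superior). All registration, statistics and landmark coordinates live
#' in world mm so grids of differing extents interoperate.
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to 1 mm isotropic
#'   with the world origin at the grid centre.
#' @return An object of class `cranio_volume` with fields `data` and `affine`.
#' @export
cranio_volume <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("volume data contains non-finite values")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(dim(data) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular")
  structure(list(data = data, affine = affine), class = "cranio_volume")
}

#' @export
print.cranio_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<cranio_volume> %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cranio_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "cranio_volume")

#' Per-axis voxel size in mm
#' @param volume A [cranio_volume].
#' @return Numeric length-3 vector of column norms of the affine 3x3 block.
#' @export
voxel_size <- function(volume) {
  sqrt(colSums(volume$affine[1:3, 1:3]^2))
}

#' Grid geometry of a volume
#'
#' A lightweight description (dimensions + affine) used as the `target`
#' argument of [resample()] so an output grid can be specified without
#' carrying pixel data.
#' @param volume A [cranio_volume] (or an existing geometry, returned as is).
#' @return List with `dim` and `affine`.
#' @export
geometry <- function(volume) {
  if (is_volume(volume)) return(list(dim = dim(volume$data), affine = volume$affine))
  if (is.list(volume) && !is.null(volume$dim) && !is.null(volume$affine)) return(volume)
  stop("expected a cranio_volume or a geometry list")
}

#' Convert between world (mm) and 0-based voxel coordinates
#' @param volume A [cranio_volume] or geometry.
#' @param points n x 3 matrix of coordinates.
#' @return n x 3 matrix in the other frame.
#' @export
world_to_voxel <- function(volume, points) {
  g <- geometry(volume)
  pts <- rbind(t(as.matrix(points)), 1)
  t(solve(g$affine) %*% pts)[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(volume, points) {
  g <- geometry(volume)
  pts <- rbind(t(as.matrix(points)), 1)
  t(g$affine %*% pts)[, 1:3, drop = FALSE]
}

#' Read / write volumes as NIfTI-1
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [cranio_volume]; `write_volume` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, but ", path, " has ", length(d), " dimensions")
  cranio_volume(array(as.numeric(img), dim = d),
                affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' @rdname read_volume
#' @param volume A [cranio_volume].
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  img <- RNifti::asNifti(volume$data, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume through a transform (pull-back convention)
#'
#' The transform maps *target* world coordinates into *source* world
#' coordinates; the output value at target voxel v is the trilinear sample of
#' the source at `transform(world(v))`. Samples outside the source
#' field of view are 0 (volumes are brain-stripped heads on an empty
#' background).
#'
#' @param volume Source [cranio_volume].
#' @param transform A [cranio_affine], a [cranio_field] (displacement added to
#'   the target point), or `NULL` for identity.
#' @param target Output geometry ([geometry()] or a volume); defaults to the
#'   source geometry.
#' @return A [cranio_volume] on the target grid.
#' @export
resample <- function(volume, transform = NULL, target = NULL) {
  stopifnot(is_volume(volume))
  g <- geometry(if (is.null(target)) volume else target)
  sdim <- dim(volume$data)
  if (is.null(transform) || is_affine(transform)) {
    m <- if (is.null(transform)) diag(4) else transform$matrix
    if (abs(det(m[1:3, 1:3])) < 1e-12)
      stop("singular transform cannot be used for resampling")
    vox_map <- solve(volume$affine) %*% m %*% g$affine
    out <- cpp_resample_affine(as.numeric(volume$data), as.integer(sdim),
                               vox_map, as.integer(g$dim))
  } else if (is_field(transform)) {
    out <- cpp_resample_field(as.numeric(volume$data), as.integer(sdim),
                              solve(volume$affine),
                              as.integer(g$dim), g$affine,
                              as.numeric(transform$disp),
                              as.integer(dim(transform$disp)[1:3]),
                              solve(transform$affine))
  } else stop("transform must be NULL, a cranio_affine or a cranio_field")
  cranio_volume(array(out, dim = g$dim), affine = g$affine)
}

#' Gaussian smoothing with a FWHM given in mm
#'
#' Separable convolution with per-axis sigma `fwhm / (2 sqrt(2 log 2))`
#' converted to voxel units, so anisotropic voxel sizes are honoured. The
#' kernel is normalised; signals supported in the interior conserve their
#' total intensity.
#'
#' @param volume A [cranio_volume].
#' @param fwhm_mm Full width at half maximum of the kernel, mm (> 0).
#' @return The blurred [cranio_volume].
#' @export
gaussian_blur <- function(volume, fwhm_mm) {
  stopifnot(is_volume(volume))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("fwhm_mm must be a positive scalar")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_size(volume)
  out <- cpp_gaussian_blur(as.numeric(volume$data), as.integer(dim(volume$data)),
                           sigma_vox)
  cranio_volume(array(out, dim = dim(volume$data)), affine = volume$affine)
}

#' Normalised cross-correlation between two volumes on a common grid
#' @param a,b Volumes on the same grid.
#' @param mask Optional logical/0-1 array restricting the comparison.
#' @return NCC in `[-1, 1]`.
#' @export
volume_ncc <- function(a, b, mask = NULL) {
  stopifnot(is_volume(a), is_volume(b), all(dim(a$data) == dim(b$data)))
  va <- as.numeric(a$data); vb <- as.numeric(b$data)
  if (!is.null(mask)) {
    keep <- as.logical(as.numeric(mask) != 0)
    va <- va[keep]; vb <- vb[keep]
  }
  if (sd(va) == 0 || sd(vb) == 0) return(0)
  stats::cor(va, vb)
}

# intensity average of a list of volumes sharing a grid
average_volumes <- function(volumes) {
  acc <- volumes[[1]]$data
  for (v in volumes[-1]) acc <- acc + v$data
  cranio_volume(acc / length(volumes), affine = volumes[[1]]$affine)
}

# crude head mask: intensity above a fraction of the robust maximum
head_mask <- function(volume, frac = 0.15) {
  mx <- quantile(volume$data[volume$data > 0], 0.99, names = FALSE)
  if (!is.finite(mx) || mx <= 0) mx <- max(volume$data)
  volume$data > frac * mx
}
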