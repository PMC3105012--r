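#' Parameterised linear transforms
#'
#' A 12-parameter affine map of world coordinates (mm), factored in the fixed
#' order `M = T %*% Rz %*% Ry %*% Rx %*% Shear %*% Scale`: scaling is applied
#' first, then shearing (unit upper-triangular), then rotation about x, y, z
#' in turn, then translation. With this order the 3x3 block is a rotation
#' times an upper-triangular matrix with positive diagonal, so the parameters
#' are recoverable from the matrix by QR factorisation (see
#' [decompose_affine()]).
#'
#' @param rotations Rotation angles about x, y, z (radians).
#' @param translations Translations (mm).
#' @param scales Per-axis scale factors (> 0).
#' @param shears Shear coefficients (xy, xz, yz) of the unit upper-triangular
#'   factor.
#' @return An object of class `cranio_affine` with `matrix` (4x4) and the
#'   generating parameters.
#' @export
affine_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                             scales = c(1, 1, 1), shears = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3, length(translations) == 3,
            length(scales) == 3, length(shears) == 3)
  if (any(scales <= 0)) stop("scales must be positive")
  m <- diag(4)
  m[1:3, 1:3] <- rotation_matrix(rotations) %*% shear_matrix(shears) %*% diag(scales)
  m[1:3, 4] <- translations
  structure(list(matrix = m,
                 rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 scales = as.numeric(scales),
                 shears = as.numeric(shears)),
            class = "cranio_affine")
}

rotation_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

shear_matrix <- function(s) {
  rbind(c(1, s[1], s[2]), c(0, 1, s[3]), c(0, 0, 1))
}

is_affine <- function(x) inherits(x, "cranio_affine")

#' Wrap an existing 4x4 matrix as a transform
#' @param m 4x4 homogeneous matrix with positive-determinant 3x3 block.
#' @return A `cranio_affine` carrying the decomposed parameters.
#' @export
affine_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  if (det(m[1:3, 1:3]) <= 0)
    stop("affine 3x3 block must have positive determinant")
  p <- decompose_affine(m)
  structure(list(matrix = m, rotations = p$rotations,
                 translations = p$translations, scales = p$scales,
                 shears = p$shears),
            class = "cranio_affine")
}

#' Recover rotations / translations / scales / shears from a matrix
#'
#' Inverts the factor order documented in [affine_transform()] by QR
#' factorisation of the 3x3 block into rotation x upper-triangular (positive
#' diagonal).
#' @param m 4x4 homogeneous matrix, positive-determinant 3x3 block.
#' @return List with `rotations`, `translations`, `scales`, `shears`.
#' @export
decompose_affine <- function(m) {
  A <- m[1:3, 1:3]
  qrd <- qr(A)
  Q <- qr.Q(qrd); Rtri <- qr.R(qrd)
  sgn <- sign(diag(Rtri)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); Rtri <- diag(sgn) %*% Rtri
  if (det(Q) < 0) stop("affine 3x3 block must have positive determinant")
  scales <- diag(Rtri)
  shears <- c(Rtri[1, 2] / scales[2], Rtri[1, 3] / scales[3],
              Rtri[2, 3] / scales[3])
  # Euler angles of Q = Rz Ry Rx
  ry <- asin(pmin(1, pmax(-1, -Q[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(Q[3, 2], Q[3, 3])
    rz <- atan2(Q[2, 1], Q[1, 1])
  } else { # gimbal lock
    rx <- atan2(-Q[2, 3], Q[2, 2])
    rz <- 0
  }
  list(rotations = c(rx, ry, rz), translations = m[1:3, 4],
       scales = scales, shears = shears)
}

#' @export
print.cranio_affine <- function(x, ...) {
  cat("<cranio_affine>\n")
  cat("  rotations (deg):", paste(sprintf("%.3f", x$rotations * 180 / pi), collapse = " "), "\n")
  cat("  translations (mm):", paste(sprintf("%.3f", x$translations), collapse = " "), "\n")
  cat("  scales:", paste(sprintf("%.4f", x$scales), collapse = " "), "\n")
  cat("  shears:", paste(sprintf("%.4f", x$shears), collapse = " "), "\n")
  invisible(x)
}

#' Invert an affine transform
#' @param transform A `cranio_affine`.
#' @return Its inverse as a `cranio_affine`.
#' @export
invert_affine <- function(transform) {
  stopifnot(is_affine(transform))
  affine_from_matrix(solve(transform$matrix))
}

#' Average affine transforms in matrix-logarithm space
#'
#' Computes `expm(mean(logm(M_i)))`. The log-space (geometric) mean is
#' inversion-symmetric: averaging a transform with its inverse yields the
#' identity, which keeps the population average head unbiased with respect to
#' the direction of registration.
#'
#' @param transforms Non-empty list of `cranio_affine` objects, all with
#'   positive-determinant 3x3 blocks.
#' @return A `cranio_affine`.
#' @export
average_affines <- function(transforms) {
  if (length(transforms) == 0) stop("need at least one transform to average")
  logs <- lapply(transforms, function(tr) {
    stopifnot(is_affine(tr))
    if (det(tr$matrix[1:3, 1:3]) <= 0)
      stop("all transforms must have positive determinant")
    pracma::logm(tr$matrix)
  })
  mlog <- Reduce(`+`, logs) / length(logs)
  m <- pracma::expm(mlog)
  m[4, ] <- c(0, 0, 0, 1) # clean numerical fuzz in the homogeneous row
  affine_from_matrix(m)
}

#' Read / write the affine text format
#'
#' Plain-text interchange: comment lines (starting with `#`) carrying the 12
#' decomposed parameters, followed by the 4 rows of the matrix,
#' whitespace-delimited.
#' @param transform A `cranio_affine`.
#' @param path Output / input file path.
#' @export
write_affine <- function(transform, path) {
  stopifnot(is_affine(transform))
  hdr <- c(
    sprintf("# rotations_rad: %s", paste(format(transform$rotations, digits = 17), collapse = " ")),
    sprintf("# translations_mm: %s", paste(format(transform$translations, digits = 17), collapse = " ")),
    sprintf("# scales: %s", paste(format(transform$scales, digits = 17), collapse = " ")),
    sprintf("# shears: %s", paste(format(transform$shears, digits = 17), collapse = " ")))
  rows <- apply(transform$matrix, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) != 4) stop("affine text file must contain 4 matrix rows: ", path)
  m <- do.call(rbind, lapply(ln, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  affine_from_matrix(m)
}
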