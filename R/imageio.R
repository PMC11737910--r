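#' Construct a 3D image volume
#'
#' Container for a 3D scalar grid (Hounsfield units for CT, dimensionless for
#' derived maps) together with its physical geometry. Patient axes are fixed
#' throughout the package: x runs right-to-left, y anterior-to-posterior,
#' z inferior-to-superior; voxel centre \code{(i, j, k)} (1-based) sits at
#' \code{origin + (c(i, j, k) - 1) * spacing} millimetres.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class \code{ctvi_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ctvi_volume")
}

#' Construct a displacement vector field
#'
#' Per-voxel displacement u(x, y, z) in mm on a fixed (reference) grid,
#' stored as a 4D array with the vector component on the last axis. By
#' convention the field maps expiration-phase positions to the corresponding
#' inspiration-phase positions: the tissue at exhale location p is found at
#' p + u(p) in the inhale image.
#'
#' @param field numeric 4D array, last dimension of length 3 (x, y, z
#'   components in mm).
#' @inheritParams image_volume
#' @return An object of class \code{ctvi_dvf}.
#' @export
dvf_field <- function(field, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(field)
  if (!is.array(field) || length(d) != 4L || d[4] != 3L)
    stop("'field' must be a 4D array with 3 components on the last axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values")
  structure(list(field = field, spacing = spacing, origin = origin),
            class = "ctvi_dvf")
}

grid_dim <- function(x) {
  if (inherits(x, "ctvi_dvf")) dim(x$field)[1:3] else dim(x$data)
}

#' @export
print.ctvi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ctvi_volume %dx%dx%d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ctvi_dvf <- function(x, ...) {
  d <- dim(x$field)
  mag <- sqrt(x$field[, , , 1]^2 + x$field[, , , 2]^2 + x$field[, , , 3]^2)
  cat(sprintf("ctvi_dvf %dx%dx%d, spacing %s mm, |u| max %.3f mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              max(mag)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop("geometry mismatch between ", what,
         ": grids and spacing/origin must agree")
  invisible(TRUE)
}

# voxel-centre coordinates (mm) along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# N x 3 matrix of all voxel-centre coordinates in mm (column-major order)
grid_points <- function(geom) {
  d <- grid_dim(geom)
  xs <- axis_coords(d[1], geom$spacing[1], geom$origin[1])
  ys <- axis_coords(d[2], geom$spacing[2], geom$origin[2])
  zs <- axis_coords(d[3], geom$spacing[3], geom$origin[3])
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

nifti_from <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  # keep the header pixdim consistent (unit fourth dimension for vector images)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
  img
}

nifti_geometry <- function(img) {
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0)) stop("non-positive voxel spacing in NIfTI header pixdim")
  dirs <- sweep(rot, 2, spacing, "/")
  if (max(abs(dirs - diag(3))) > 1e-4)
    stop("NIfTI qform/sform axes are rotated or flipped relative to the ",
         "package patient-axis convention; only axis-aligned volumes are supported")
  list(spacing = as.numeric(spacing), origin = as.numeric(aff[1:3, 4]))
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path path to a .nii or .nii.gz file holding a single 3D volume with
#'   axis-aligned orientation.
#' @return A \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, but '", basename(path), "' has dim = (",
         paste(d, collapse = ", "), ")")
  g <- nifti_geometry(img)
  image_volume(array(as.numeric(img), dim = d), g$spacing, g$origin)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param v a \code{\link{image_volume}}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ctvi_volume"))
  RNifti::writeNifti(nifti_from(v$data, v$spacing, v$origin), path)
  invisible(path)
}

#' Read a displacement field from 4D NIfTI
#'
#' The file must be 4D with exactly 3 components on the last axis,
#' interpreted as (x, y, z) displacements in mm in patient axes.
#'
#' @param path path to a 4D NIfTI file.
#' @param reference optional \code{ctvi_volume}; if given, the field geometry
#'   must match it exactly.
#' @return A \code{\link{dvf_field}}.
#' @export
read_dvf <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D NIfTI with 3 vector components on the last axis, ",
         "but '", basename(path), "' has dim = (", paste(d, collapse = ", "), ")")
  g <- nifti_geometry(img)
  f <- dvf_field(array(as.numeric(img), dim = d), g$spacing, g$origin)
  if (!is.null(reference)) stop_geometry(f, reference, "displacement field and reference volume")
  f
}

#' Write a displacement field as 4D NIfTI
#'
#' @param f a \code{\link{dvf_field}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dvf <- function(f, path) {
  stopifnot(inherits(f, "ctvi_dvf"))
  RNifti::writeNifti(nifti_from(f$field, f$spacing, f$origin), path)
  invisible(path)
}

#' Read a label mask from NIfTI-1
#'
#' @param path path to a 3D NIfTI of integer labels.
#' @return A \code{ctvi_volume} with integer data.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$data <- array(as.integer(round(v$data)), dim = dim(v$data))
  v
}
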