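#' Regional displacement-vector statistics
#'
#' Summarises the displacement field over a region: mean displacement vector
#' and magnitude, the gravity-alignment index (magnitude-weighted mean cosine
#' between per-voxel displacement and the gravity direction, so +1 means
#' motion with gravity, -1 against it, 0 parallel to the ground), and ground
#' parallelism (mean over voxels of the magnitude of the unit-vector
#' component orthogonal to gravity). Voxels with |u| below the magnitude
#' floor carry no reliable orientation and are excluded from the two
#' orientation statistics; if no voxel passes the floor both are NA.
#'
#' @param dvf a \code{\link{dvf_field}}.
#' @param region logical array, label array or mask volume; positive/true
#'   voxels define the region.
#' @param gravity unit 3-vector (see \code{\link{gravity_vector}}).
#' @param floor_mm magnitude floor in mm (default 0.5).
#' @return A one-row data.frame: n_voxels, mean_ux/uy/uz, mean_magnitude_mm,
#'   gravity_alignment, ground_parallelism, n_oriented.
#' @export
region_vector_summary <- function(dvf, region, gravity, floor_mm = 0.5) {
  stopifnot(inherits(dvf, "ctvi_dvf"))
  gn <- sqrt(sum(gravity^2))
  if (gn == 0) stop("gravity vector must be nonzero")
  if (abs(gn - 1) > 1e-6) gravity <- gravity / gn
  idx <- mask_indices(region)
  if (length(idx) == 0L) stop("empty region")
  nvox <- prod(grid_dim(dvf))
  uf <- dvf$field
  dim(uf) <- c(nvox, 3)
  u <- uf[idx, , drop = FALSE]
  mag <- sqrt(rowSums(u^2))
  proj <- as.numeric(u %*% gravity)
  ok <- mag >= floor_mm
  if (any(ok)) {
    alignment <- sum(proj[ok]) / sum(mag[ok])
    par_comp <- sqrt(pmax(0, 1 - (proj[ok] / mag[ok])^2))
    parallelism <- mean(par_comp)
  } else {
    alignment <- NA_real_
    parallelism <- NA_real_
  }
  data.frame(n_voxels = length(idx),
             mean_ux = mean(u[, 1]), mean_uy = mean(u[, 2]), mean_uz = mean(u[, 3]),
             mean_magnitude_mm = mean(mag),
             gravity_alignment = alignment,
             ground_parallelism = parallelism,
             n_oriented = sum(ok))
}

#' Export displacement arrows for quiver plotting
#'
#' Subsamples the field on a regular stride grid inside a mask and returns a
#' table of arrow positions (mm), vectors (mm) and magnitudes, ordered by
#' flattened voxel index so output is deterministic.
#'
#' @param dvf a \code{\link{dvf_field}}.
#' @param mask region mask (logical, labels or mask volume).
#' @param stride stride in voxels (>= 1) along every axis.
#' @return A data.frame with columns x, y, z, ux, uy, uz, magnitude_mm.
#' @export
export_arrows <- function(dvf, mask, stride = 4L) {
  stopifnot(inherits(dvf, "ctvi_dvf"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1")
  d <- grid_dim(dvf)
  sel <- array(FALSE, dim = d)
  sel[seq.int(1L, d[1], stride), seq.int(1L, d[2], stride),
      seq.int(1L, d[3], stride)] <- TRUE
  if (inherits(mask, "ctvi_volume")) mask <- mask$data
  inmask <- if (is.logical(mask)) mask else mask > 0
  idx <- which(sel & inmask)
  pts <- grid_points(dvf)[idx, , drop = FALSE]
  nvox <- prod(d)
  uf <- dvf$field
  dim(uf) <- c(nvox, 3)
  u <- uf[idx, , drop = FALSE]
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             ux = u[, 1], uy = u[, 2], uz = u[, 3],
             magnitude_mm = sqrt(rowSums(u^2)))
}
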