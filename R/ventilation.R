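#' Jacobian-determinant ventilation map
#'
#' Computes the local volume-change factor V(x, y, z) = det(I + grad u) of a
#' displacement field by finite differences: central differences in the grid
#' interior and one-sided differences at the boundary, each derivative
#' divided by the physical voxel spacing of its axis. V > 1 marks local
#' tissue expansion, V < 1 contraction, and V = 1 no volume change; on a zero
#' field the map is exactly 1 everywhere.
#'
#' @param dvf a \code{\link{dvf_field}} in mm.
#' @return A \code{ctvi_volume} of dimensionless determinant values on the
#'   field's grid.
#' @export
jacobian_map <- function(dvf) {
  stopifnot(inherits(dvf, "ctvi_dvf"))
  d <- grid_dim(dvf)
  if (any(d < 3L))
    stop("degenerate grid: every axis needs at least 3 voxels for finite differences")
  sp <- dvf$spacing
  # g[[j]][[i]] = d u_i / d axis_j
  g <- lapply(1:3, function(ax)
    lapply(1:3, function(comp) diff_axis(dvf$field[, , , comp], ax, sp[ax])))
  a11 <- 1 + g[[1]][[1]]; a12 <- g[[2]][[1]]; a13 <- g[[3]][[1]]
  a21 <- g[[1]][[2]]; a22 <- 1 + g[[2]][[2]]; a23 <- g[[3]][[2]]
  a31 <- g[[1]][[3]]; a32 <- g[[2]][[3]]; a33 <- 1 + g[[3]][[3]]
  v <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
       a13 * (a21 * a32 - a22 * a31)
  image_volume(array(v, dim = d), sp, dvf$origin)
}

mask_indices <- function(mask) {
  if (inherits(mask, "ctvi_volume")) mask <- mask$data
  if (is.logical(mask)) which(mask) else which(mask > 0)
}

#' Percentile conversion of a ventilation map
#'
#' Converts Jacobian values to percentile ranks within a reference voxel
#' population (normally all voxels of both lungs combined). The rank of a
#' voxel is 100 * (number of in-mask voxels with strictly smaller value +
#' half the ties) / N, so a constant map ranks 50 everywhere and ranks are
#' invariant under strictly monotone transforms of the values.
#'
#' @param jac a \code{ctvi_volume} of Jacobian values.
#' @param mask reference population: a logical array, a label array, or a
#'   \code{ctvi_volume} mask (positive labels are in-mask).
#' @return A \code{ctvi_volume} of percentile ranks in [0, 100]; voxels
#'   outside the mask are NA. The mask is kept in attribute \code{"mask"}.
#' @export
percentile_map <- function(jac, mask) {
  stopifnot(inherits(jac, "ctvi_volume"))
  if (inherits(mask, "ctvi_volume")) stop_geometry(jac, mask, "map and mask")
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("empty mask: percentile reference population is empty")
  v <- jac$data[idx]
  n <- length(v)
  ranks <- 100 * (rank(v, ties.method = "average") - 0.5) / n
  out <- array(NA_real_, dim = dim(jac$data))
  out[idx] <- ranks
  p <- image_volume(out, jac$spacing, jac$origin)
  attr(p, "mask") <- idx
  p
}

#' Highly functional lung regions
#'
#' Flags voxels whose percentile rank is at or above a threshold; with the
#' default 75th-percentile threshold the flagged voxels are the top quartile
#' of the in-mask Jacobian distribution (exactly N/4 voxels when all values
#' are distinct and N is divisible by 4).
#'
#' @param pmap a percentile map from \code{\link{percentile_map}}.
#' @param threshold percentile in (0, 100); default 75.
#' @return A \code{ctvi_volume} with integer data: 1 for highly functional
#'   voxels, 0 elsewhere (including outside the mask).
#' @export
functional_mask <- function(pmap, threshold = 75) {
  stopifnot(inherits(pmap, "ctvi_volume"))
  if (threshold <= 0 || threshold >= 100)
    stop("'threshold' must lie strictly between 0 and 100")
  flag <- !is.na(pmap$data) & pmap$data >= threshold
  image_volume(array(as.integer(flag), dim = dim(pmap$data)),
               pmap$spacing, pmap$origin)
}
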