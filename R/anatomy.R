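#' Segment left and right lungs from CT
#'
#' Threshold segmentation for HU-calibrated thoracic CT: voxels below -400 HU
#' are air candidates; connected components touching the grid border (ambient
#' air) are removed; the two largest remaining components become the lungs,
#' labelled by centroid along the x (right-to-left) axis. If only one
#' component remains and it straddles the mid-sagittal plane it is split
#' there; a genuinely single lung (one-sided component) is labelled alone.
#'
#' @param ct a \code{ctvi_volume} in HU.
#' @param threshold_hu air/parenchyma threshold (default -400).
#' @param min_voxels components smaller than this are ignored (default 50).
#' @return A \code{ctvi_volume} label mask: 0 background, 1 left lung,
#'   2 right lung.
#' @export
segment_lungs <- function(ct, threshold_hu = -400, min_voxels = 50L) {
  stopifnot(inherits(ct, "ctvi_volume"))
  d <- dim(ct$data)
  air <- ct$data < threshold_hu
  lab <- cpp_label3d(air, d)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  keep <- tabulate(lab)
  cand <- setdiff(which(keep >= min_voxels), border)
  if (length(cand) < 1L)
    stop("lung segmentation failed: no interior air component found")
  cand <- cand[order(keep[cand], decreasing = TRUE)]
  cand <- cand[seq_len(min(2L, length(cand)))]
  out <- array(0L, dim = d)
  xs_mid <- (d[1] + 1) / 2
  if (length(cand) == 2L) {
    cx <- vapply(cand, function(l) mean(which(lab == l, arr.ind = TRUE)[, 1]), 0)
    left <- cand[which.max(cx)]   # left lung lies at larger x (right-to-left axis)
    out[lab == left] <- 1L
    out[lab == cand[cand != left]] <- 2L
  } else {
    vox <- which(lab == cand, arr.ind = TRUE)
    fr_right <- mean(vox[, 1] < xs_mid)
    if (fr_right > 0.25 && fr_right < 0.75) {
      # fused lungs: split at the mid-sagittal plane
      out[lab == cand] <- 1L
      out[vox[vox[, 1] < xs_mid, , drop = FALSE]] <- 2L
    } else if (fr_right >= 0.75) {
      out[lab == cand] <- 2L
    } else {
      out[lab == cand] <- 1L
    }
  }
  image_volume(out, ct$spacing, ct$origin)
}

#' Lung volume in millilitres
#'
#' Voxel count times voxel volume (mm^3) divided by 1000.
#'
#' @param mask a label mask (0 background, 1 left, 2 right).
#' @param lung "left", "right" or "total".
#' @return Volume in mL.
#' @export
lung_volume <- function(mask, lung = c("total", "left", "right")) {
  stopifnot(inherits(mask, "ctvi_volume"))
  lung <- match.arg(lung)
  n <- switch(lung,
              total = sum(mask$data > 0),
              left = sum(mask$data == 1),
              right = sum(mask$data == 2))
  n * prod(mask$spacing) / 1000
}

#' Define cranio-caudal lung sections
#'
#' Places four axial slabs (apical, middle, basal, diaphragm) at fractional
#' cranio-caudal positions within the lung extent: a fraction f gives a slab
#' centred f of the way from the apex (most cranial lung slice) to the base.
#' Anatomical landmarks (aortic arch, carina, heart, diaphragm dome) are not
#' available on phantoms, so fractional positions stand in for the landmark
#' levels; slabs of a few slices are used for robustness, and a thickness of
#' 1 restores single-slice sections.
#'
#' @param mask lung label mask.
#' @param fractions length-4 increasing fractions in [0, 1] for
#'   apical/middle/basal/diaphragm (defaults 0.15, 0.40, 0.65, 0.88).
#' @param slab_thickness slab thickness in slices (odd, default 3).
#' @return A \code{section_set}: named list of z-slice index vectors plus the
#'   parameters used.
#' @export
define_sections <- function(mask, fractions = c(0.15, 0.40, 0.65, 0.88),
                            slab_thickness = 3L) {
  stopifnot(inherits(mask, "ctvi_volume"))
  if (length(fractions) != 4L || is.unsorted(fractions) ||
      any(fractions < 0 | fractions > 1))
    stop("'fractions' must be 4 increasing values in [0, 1]")
  slab_thickness <- as.integer(slab_thickness)
  if (slab_thickness < 1L) stop("'slab_thickness' must be >= 1")
  zs <- which(apply(mask$data > 0, 3, any))
  if (length(zs) == 0L) stop("empty lung mask")
  apex <- max(zs)   # z runs inferior to superior: the apex is the top slice
  base <- min(zs)
  centers <- round(apex - fractions * (apex - base))
  half <- (slab_thickness - 1L) %/% 2L
  slices <- lapply(centers, function(cz)
    seq.int(max(base, cz - half), min(apex, cz + half)))
  names(slices) <- c("apical", "middle", "basal", "diaphragm")
  for (i in 1:3)
    if (length(intersect(slices[[i]], slices[[i + 1]])) > 0)
      stop("sections overlap: reduce 'slab_thickness' or spread 'fractions'")
  structure(list(slices = slices, fractions = fractions,
                 slab_thickness = slab_thickness,
                 lung_z_range = c(base = base, apex = apex)),
            class = "section_set")
}

#' Highly-functional-area ratios per lung and section
#'
#' For every lung and cranio-caudal section, the percentage of section-lung
#' voxels flagged highly functional, together with the section-lung volume in
#' mL. Empty section-lung intersections yield NA ratios (flagged, not zero).
#'
#' @param hf_mask binary highly-functional mask (from
#'   \code{\link{functional_mask}}).
#' @param lungs lung label mask (1 left, 2 right).
#' @param sections a \code{section_set} from \code{\link{define_sections}}.
#' @return A data.frame with columns lung, section, ratio_pct, volume_ml,
#'   n_voxels.
#' @export
functional_ratio <- function(hf_mask, lungs, sections) {
  stopifnot(inherits(hf_mask, "ctvi_volume"), inherits(lungs, "ctvi_volume"),
            inherits(sections, "section_set"))
  stop_geometry(hf_mask, lungs, "functional mask and lung mask")
  vox_ml <- prod(lungs$spacing) / 1000
  rows <- list()
  for (lg in c("right", "left")) {
    lab <- if (lg == "left") 1L else 2L
    for (sec in names(sections$slices)) {
      sl <- sections$slices[[sec]]
      lmask <- lungs$data[, , sl, drop = FALSE] == lab
      nvox <- sum(lmask)
      nhf <- sum(hf_mask$data[, , sl, drop = FALSE][lmask] > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        lung = lg, section = sec,
        ratio_pct = if (nvox > 0) 100 * nhf / nvox else NA_real_,
        volume_ml = nvox * vox_ml, n_voxels = nvox,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$section <- factor(out$section, levels = names(sections$slices))
  out
}
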