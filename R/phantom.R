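#' Gravity direction for a body position
#'
#' Patient axes are x right-to-left, y anterior-to-posterior, z
#' inferior-to-superior. The returned unit vector points "down", i.e. toward
#' the dependent side: +y when supine (the back is down), -y when prone,
#' toward patient-right (-x) in right lateral decubitus and toward
#' patient-left (+x) in left lateral decubitus.
#'
#' @param position one of "supine", "prone", "right_lateral", "left_lateral".
#' @return Unit 3-vector in patient axes.
#' @export
gravity_vector <- function(position) {
  switch(match.arg(position, c("supine", "prone", "right_lateral", "left_lateral")),
         supine = c(0, 1, 0),
         prone = c(0, -1, 0),
         right_lateral = c(-1, 0, 0),
         left_lateral = c(1, 0, 0))
}

# Per-position split of the global volume expansion across patient axes
# (fraction of log expansion assigned to x, y, z), and the bulk anti-gravity
# drift of the lung region in mm. Supine breathing is chest-wall dominated
# (y), prone breathing is cranio-caudal (z, diaphragm) with almost no motion
# along gravity, lateral positions are mixed.
position_axis_weights <- function(position) {
  switch(position,
         supine = c(0.20, 0.40, 0.40),
         prone = c(0.48, 0.06, 0.46),
         right_lateral = c(0.28, 0.30, 0.42),
         left_lateral = c(0.28, 0.30, 0.42))
}

position_bulk_shift <- function(position) {
  switch(position, supine = 6, prone = 0, right_lateral = 3, left_lateral = 3)
}

#' Specify a synthetic thorax phantom
#'
#' Describes a digital thorax used to emulate paired expiration/inspiration
#' breath-hold CT with a known ground-truth displacement field: an elliptical
#' soft-tissue body containing two ellipsoidal lungs and a spine, imaged at
#' exhale, then deformed by a smooth analytic field whose mean Jacobian over
#' the lungs equals \code{global_expansion} and whose local expansion
#' increases toward the dependent (gravity) side and toward the diaphragm.
#'
#' @param grid_shape integer length-3, voxels per axis (default 96^3).
#' @param spacing_mm voxel size in mm (default 2 mm isotropic).
#' @param position body position; sets the gravity axis and the per-axis
#'   partition of the expansion (see \code{\link{gravity_vector}}).
#' @param global_expansion target mean ground-truth Jacobian over the lungs;
#'   the default 1.30 mirrors a typical tidal inhale/exhale lung volume ratio.
#' @param gravity_gradient dimensionless slope of the Jacobian along the
#'   gravity axis across the lung half-extent; the dependent side expands more.
#' @param diaphragm_gradient dimensionless slope of the Jacobian along the
#'   cranio-caudal axis; expansion increases toward the diaphragm.
#' @param lung_geometry list with \code{center_offset_mm} (lateral offset of
#'   each lung centre from the midline) and \code{semi_axes_mm} (ellipsoid
#'   semi-axes); defaults fit the default grid.
#' @param tissue_hu named list of HU values: \code{lung}, \code{soft},
#'   \code{spine}, \code{air}.
#' @param axis_weights optional length-3 positive weights overriding the
#'   per-position partition of log expansion across axes (normalised to sum 1).
#' @param bulk_shift_mm optional bulk anti-gravity drift of the lung region in
#'   mm (default depends on position).
#' @param density_rescale logical; if TRUE (default) warped HU are rescaled as
#'   \code{-1000 + (HU + 1000) / J} so local expansion dilutes parenchymal
#'   density, giving ventilation an intensity signature.
#' @param texture_amp_hu amplitude (SD, HU) of the smooth parenchymal texture
#'   inside the lungs; gives intensity-based registration local contrast.
#' @param texture_spacing_mm correlation length of the texture in mm.
#' @param psf_passes scanner point-spread emulation: separable binomial
#'   smoothing passes applied to each rendered phase before noise (default 1,
#'   about a 0.7-voxel sigma, mimicking a CT reconstruction kernel and the
#'   partial-volume effect at tissue boundaries). 0 disables.
#' @param noise_sd_hu additive Gaussian image noise SD in HU (default 20).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return A validated \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing_mm = c(2, 2, 2),
                         position = "supine",
                         global_expansion = 1.30,
                         gravity_gradient = 0.15,
                         diaphragm_gradient = 0.10,
                         lung_geometry = NULL,
                         tissue_hu = list(lung = -780, soft = 40, spine = 700, air = -1000),
                         axis_weights = NULL,
                         bulk_shift_mm = NULL,
                         density_rescale = TRUE,
                         texture_amp_hu = 100,
                         texture_spacing_mm = 10,
                         psf_passes = 1L,
                         noise_sd_hu = 20,
                         seed = 1L) {
  position <- match.arg(position, c("supine", "prone", "right_lateral", "left_lateral"))
  grid_shape <- as.integer(grid_shape)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("'grid_shape' must be 3 integers >= 16")
  if (any(spacing_mm <= 0)) stop("'spacing_mm' must be strictly positive")
  if (!is.finite(global_expansion) || global_expansion <= 0)
    stop("'global_expansion' must be > 0")
  if (gravity_gradient < 0 || gravity_gradient > 0.5)
    stop("'gravity_gradient' must lie in [0, 0.5]")
  if (is.null(lung_geometry))
    lung_geometry <- list(center_offset_mm = 30, semi_axes_mm = c(26, 36, 50))
  if (is.null(axis_weights)) axis_weights <- position_axis_weights(position)
  axis_weights <- axis_weights / sum(axis_weights)
  if (is.null(bulk_shift_mm)) bulk_shift_mm <- position_bulk_shift(position)
  spec <- list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
               position = position, global_expansion = global_expansion,
               gravity_gradient = gravity_gradient,
               diaphragm_gradient = diaphragm_gradient,
               lung_geometry = lung_geometry, tissue_hu = tissue_hu,
               axis_weights = as.numeric(axis_weights),
               bulk_shift_mm = bulk_shift_mm,
               density_rescale = isTRUE(density_rescale),
               texture_amp_hu = texture_amp_hu,
               texture_spacing_mm = texture_spacing_mm,
               psf_passes = as.integer(psf_passes),
               noise_sd_hu = noise_sd_hu, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# evaluate with a temporary, restorable RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

smoothstep <- function(e0, e1, x) {
  t <- pmin(pmax((x - e0) / (e1 - e0), 0), 1)
  t * t * (3 - 2 * t)
}

# internal geometry derived from a phantom spec (all in mm)
phantom_geometry <- function(spec) {
  n <- spec$grid_shape; sp <- spec$spacing_mm
  origin <- c(0, 0, 0)
  centre <- (n - 1) * sp / 2
  body_semi_xy <- c(80, 70)
  body_half_z <- centre[3] - max(6, 2 * sp[3])
  lg <- spec$lung_geometry
  semi <- lg$semi_axes_mm
  off <- lg$center_offset_mm
  list(origin = origin, centre = centre,
       body_semi_xy = body_semi_xy, body_half_z = body_half_z,
       lung_semi = semi,
       lung_centres = rbind(right = c(centre[1] - off, centre[2], centre[3]),
                            left = c(centre[1] + off, centre[2], centre[3])),
       taper_flat_rho = 0.72, z_flat = semi[3] + 2,
       spine_centre_xy = c(centre[1], centre[2] + 46), spine_radius = 12)
}

# membership helpers on coordinate vectors
inside_body <- function(g, px, py, pz) {
  rho2 <- ((px - g$centre[1]) / g$body_semi_xy[1])^2 +
          ((py - g$centre[2]) / g$body_semi_xy[2])^2
  rho2 <= 1 & abs(pz - g$centre[3]) <= g$body_half_z
}

lung_label_at <- function(g, px, py, pz) {
  lab <- integer(length(px))
  for (side in c("right", "left")) {
    lc <- g$lung_centres[side, ]
    r2 <- ((px - lc[1]) / g$lung_semi[1])^2 + ((py - lc[2]) / g$lung_semi[2])^2 +
          ((pz - lc[3]) / g$lung_semi[3])^2
    lab[r2 <= 1] <- if (side == "left") 1L else 2L
  }
  lab
}

# Analytic ground-truth displacement closure for a spec. Returns a list with
# u(px, py, pz) -> N x 3 matrix (mm), the closed-form core Jacobian
# jac_core(px, py, pz), and the calibrated per-axis strain parameters.
phantom_truth_field <- function(spec, g) {
  grav <- gravity_vector(spec$position)
  gaxis <- which(grav != 0)
  gsign <- grav[gaxis]
  # half-extent of the combined lung region along each axis
  L <- c(spec$lung_geometry$center_offset_mm + g$lung_semi[1],
         g$lung_semi[2], g$lung_semi[3])
  # Jacobian slope per axis: gravity gradient (dependent side expands more)
  # plus the cranio-caudal diaphragm gradient (basal side expands more)
  s <- c(0, 0, -spec$diaphragm_gradient)
  s[gaxis] <- s[gaxis] + spec$gravity_gradient * gsign
  # initial per-axis linear expansion factors from the axis partition
  e <- spec$global_expansion^spec$axis_weights
  # calibrate so the mean core Jacobian over the exhale lung voxels is exact
  cc <- g$centre
  core_jac <- function(px, py, pz, ee) {
    (ee[1] * (1 + s[1] * (px - cc[1]) / L[1])) *
    (ee[2] * (1 + s[2] * (py - cc[2]) / L[2])) *
    (ee[3] * (1 + s[3] * (pz - cc[3]) / L[3]))
  }
  spx <- spec$spacing_mm
  xs <- axis_coords(spec$grid_shape[1], spx[1], g$origin[1])
  ys <- axis_coords(spec$grid_shape[2], spx[2], g$origin[2])
  zs <- axis_coords(spec$grid_shape[3], spx[3], g$origin[3])
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  in_lung <- lung_label_at(g, pts[, 1], pts[, 2], pts[, 3]) > 0L
  m <- mean(core_jac(pts[in_lung, 1], pts[in_lung, 2], pts[in_lung, 3], e))
  e <- e * (spec$global_expansion / m)^spec$axis_weights

  # anchors: centred on x and y, except the z axis is anchored at the lung
  # apex (the diaphragm descends, the apex stays); the bulk drift is a
  # rigid-body shift of the lung region opposite to gravity
  t0 <- cc
  t0[3] <- cc[3] + L[3]
  bulk <- -grav * spec$bulk_shift_mm

  taper <- function(px, py, pz) {
    rho <- sqrt(((px - cc[1]) / g$body_semi_xy[1])^2 +
                ((py - cc[2]) / g$body_semi_xy[2])^2)
    wr <- 1 - smoothstep(g$taper_flat_rho, 1, rho)
    wz <- 1 - smoothstep(g$z_flat, g$body_half_z, abs(pz - cc[3]))
    wr * wz
  }
  axis_u <- function(t, k) {
    # integral of (e_k (1 + s_k (t - c)/L_k) - 1) dt from t0_k to t
    a <- e[k] - 1
    b <- e[k] * s[k] / (2 * L[k])
    (a * (t - t0[k]) + b * ((t - cc[k])^2 - (t0[k] - cc[k])^2))
  }
  u_eval <- function(px, py, pz) {
    w <- taper(px, py, pz)
    cbind(w * (axis_u(px, 1) + bulk[1]),
          w * (axis_u(py, 2) + bulk[2]),
          w * (axis_u(pz, 3) + bulk[3]))
  }
  list(u = u_eval,
       jac_core = function(px, py, pz) core_jac(px, py, pz, e),
       taper = taper, e = e, s = s, L = L, anchors = t0, bulk = bulk,
       gravity = grav)
}

# numerical Jacobian of an analytic field at arbitrary points (central
# differences, h in mm)
numeric_jacobian_at <- function(u_eval, px, py, pz, h = 0.25) {
  d <- vector("list", 3)
  offs <- diag(3) * h
  for (k in 1:3) {
    up <- u_eval(px + offs[1, k], py + offs[2, k], pz + offs[3, k])
    um <- u_eval(px - offs[1, k], py - offs[2, k], pz - offs[3, k])
    d[[k]] <- (up - um) / (2 * h)   # N x 3: d u / d axis_k
  }
  a11 <- 1 + d[[1]][, 1]; a12 <- d[[2]][, 1]; a13 <- d[[3]][, 1]
  a21 <- d[[1]][, 2]; a22 <- 1 + d[[2]][, 2]; a23 <- d[[3]][, 2]
  a31 <- d[[1]][, 3]; a32 <- d[[2]][, 3]; a33 <- 1 + d[[3]][, 3]
  a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Generate a synthetic exhale/inhale CT pair with ground truth
#'
#' Renders the exhale CT from the phantom geometry, builds the analytic
#' ground-truth displacement field u (expiration to inspiration, zero outside
#' the body), and produces the inhale CT by resampling the exhale scene
#' through the inverse deformation, optionally rescaling HU by 1/J so that
#' local expansion dilutes density. Gaussian noise is added independently to
#' both phases.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{phantom_pair} list with elements \code{exhale},
#'   \code{inhale} (\code{ctvi_volume}), \code{truth_dvf} (\code{ctvi_dvf} on
#'   the exhale grid), \code{truth_lungs} and \code{truth_lungs_inhale}
#'   (label masks, 1 = left, 2 = right), \code{gravity} (unit vector),
#'   \code{jac_core} (closed-form Jacobian of the untapered core, a function
#'   of mm coordinates), \code{mean_lung_jacobian}, and the \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  # lungs must sit inside the flat (untapered) core of the body
  lc <- g$lung_centres; semi <- g$lung_semi
  worst_rho <- max(sqrt(((abs(lc[, 1] - g$centre[1]) + semi[1]) / g$body_semi_xy[1])^2),
                   sqrt((abs(lc[1, 1] - g$centre[1]) / g$body_semi_xy[1])^2 +
                        (semi[2] / g$body_semi_xy[2])^2))
  if (worst_rho > g$taper_flat_rho || semi[3] + 2 > g$body_half_z)
    stop("lung ellipsoids are not fully inside the body core; ",
         "reduce 'lung_geometry' or enlarge the grid")

  tf <- phantom_truth_field(spec, g)
  n <- spec$grid_shape; sp <- spec$spacing_mm
  nvox <- prod(n)
  xs <- axis_coords(n[1], sp[1], g$origin[1])
  ys <- axis_coords(n[2], sp[2], g$origin[2])
  zs <- axis_coords(n[3], sp[3], g$origin[3])
  px <- rep(xs, times = n[2] * n[3])
  py <- rep(rep(ys, each = n[1]), times = n[3])
  pz <- rep(zs, each = n[1] * n[2])

  hu <- spec$tissue_hu
  # seeded smooth texture field, evaluable anywhere in the domain
  tex_sp <- spec$texture_spacing_mm
  tex_dim <- as.integer(ceiling((n - 1) * sp / tex_sp) + 4L)
  tex <- with_local_seed(spec$seed, list(
    grid = array(stats::rnorm(prod(tex_dim), sd = spec$texture_amp_hu), dim = tex_dim),
    noise_ex = stats::rnorm(nvox, sd = spec$noise_sd_hu),
    noise_in = stats::rnorm(nvox, sd = spec$noise_sd_hu)))
  tex_origin <- g$origin - 1.5 * tex_sp
  render <- function(qx, qy, qz) {
    out <- rep(hu$air, length(qx))
    body <- inside_body(g, qx, qy, qz)
    out[body] <- hu$soft
    lab <- lung_label_at(g, qx, qy, qz)
    lung <- lab > 0L
    if (any(lung)) {
      t <- cpp_sample3(tex$grid, dim(tex$grid), rep(tex_sp, 3), tex_origin,
                       cbind(qx[lung], qy[lung], qz[lung]), 1L, 0)
      out[lung] <- pmin(hu$lung + t, -500)  # keep parenchyma below air threshold
    }
    spine <- body & ((qx - g$spine_centre_xy[1])^2 +
                     (qy - g$spine_centre_xy[2])^2) <= g$spine_radius^2
    out[spine] <- hu$spine
    out
  }

  exhale_clean <- render(px, py, pz)
  truth_labels <- lung_label_at(g, px, py, pz)

  u <- tf$u(px, py, pz)
  field <- array(u, dim = c(n, 3))
  truth_dvf <- dvf_field(field, sp, g$origin)
  rm(u, field)

  # folding guard on the discrete ground-truth Jacobian inside the body
  jac_num <- numeric_jacobian_at(function(ax, ay, az) tf$u(ax, ay, az),
                                 px, py, pz, h = 0.5)
  body_mask <- inside_body(g, px, py, pz)
  if (min(jac_num[body_mask]) <= 0.01)
    stop("ground-truth deformation folds (Jacobian <= 0 inside the body); ",
         "reduce 'global_expansion', gradients or bulk shift")
  in_lung <- truth_labels > 0L
  mean_j <- mean(jac_num[in_lung])

  # inhale: invert y = x + u(x) by fixed-point iteration, then resample
  cand <- body_mask
  ix <- px[cand]; iy <- py[cand]; iz <- pz[cand]
  tx <- ix; ty <- iy; tz <- iz
  for (it in 1:30) {
    uu <- tf$u(tx, ty, tz)
    tx <- ix - uu[, 1]; ty <- iy - uu[, 2]; tz <- iz - uu[, 3]
  }
  inhale_clean <- exhale_clean
  vals <- render(tx, ty, tz)
  src_lung <- lung_label_at(g, tx, ty, tz)
  if (spec$density_rescale) {
    # density dilution applies to aerated parenchyma only; soft tissue is
    # incompressible and keeps its HU
    jinv <- numeric_jacobian_at(function(ax, ay, az) tf$u(ax, ay, az),
                                tx, ty, tz, h = 0.5)
    il <- src_lung > 0L
    vals[il] <- -1000 + (vals[il] + 1000) / jinv[il]
  }
  inhale_clean[cand] <- vals
  inhale_labels <- integer(nvox)
  inhale_labels[cand] <- src_lung

  if (spec$psf_passes > 0L) {
    # scanner point-spread: the reconstruction kernel blurs the physical
    # scene after deformation, so it is applied to each rendered phase
    exhale_clean <- as.numeric(smooth3(array(exhale_clean, dim = n), spec$psf_passes))
    inhale_clean <- as.numeric(smooth3(array(inhale_clean, dim = n), spec$psf_passes))
  }
  exhale <- image_volume(array(exhale_clean + tex$noise_ex, dim = n), sp, g$origin)
  inhale <- image_volume(array(inhale_clean + tex$noise_in, dim = n), sp, g$origin)
  truth_lungs <- image_volume(array(truth_labels, dim = n), sp, g$origin)
  truth_lungs_inhale <- image_volume(array(inhale_labels, dim = n), sp, g$origin)
  rm(exhale_clean, inhale_clean, vals, tex, jac_num, tx, ty, tz, px, py, pz)
  gc(verbose = FALSE)   # large-grid temporaries; return pages before heavy callers

  structure(list(exhale = exhale, inhale = inhale, truth_dvf = truth_dvf,
                 truth_lungs = truth_lungs,
                 truth_lungs_inhale = truth_lungs_inhale,
                 gravity = tf$gravity, jac_core = tf$jac_core,
                 mean_lung_jacobian = mean_j, spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("phantom_pair: %s, %s voxels @ %.3g mm, mean lung Jacobian %.3f\n",
              x$spec$position, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$spacing_mm[1], x$mean_lung_jacobian))
  invisible(x)
}

#' Analytic displacement fields with known Jacobians
#'
#' Constructs oracle displacement fields on a given grid geometry for testing
#' the Jacobian ventilation metric: \code{affine} fields u = A x + b whose
#' Jacobian is det(I + A) everywhere, \code{gravity_gradient} fields varying
#' linearly along a direction with a linear closed-form Jacobian, and seeded
#' \code{smooth_random} B-spline fields (no closed form attached).
#'
#' @param kind one of "affine", "gravity_gradient", "smooth_random".
#' @param params list of parameters. For \code{affine}: \code{A} (3x3 matrix)
#'   and optional \code{offset} (mm). For \code{gravity_gradient}:
#'   \code{direction} (3-vector, normalised internally), \code{base} (strain
#'   at the centre), \code{slope} (strain per mm), optional \code{center}
#'   (mm, defaults to the grid centre). For \code{smooth_random}:
#'   \code{amplitude_mm}, \code{control_spacing_mm}, \code{seed}.
#' @param grid an object with grid geometry (\code{ctvi_volume} or
#'   \code{ctvi_dvf}), or a list with \code{dim}, \code{spacing},
#'   \code{origin}.
#' @return A \code{\link{dvf_field}}; for the first two kinds the attribute
#'   \code{"jacobian_fun"} holds a function of (x, y, z) coordinate vectors
#'   (mm) returning the closed-form Jacobian.
#' @export
analytic_dvf <- function(kind = c("affine", "gravity_gradient", "smooth_random"),
                         params = list(), grid) {
  kind <- match.arg(kind)
  if (inherits(grid, "ctvi_volume") || inherits(grid, "ctvi_dvf")) {
    gdim <- grid_dim(grid); gsp <- grid$spacing; gor <- grid$origin
  } else {
    gdim <- grid$dim; gsp <- grid$spacing
    gor <- if (is.null(grid$origin)) c(0, 0, 0) else grid$origin
  }
  pts <- grid_points(list(data = array(0, dim = gdim), spacing = gsp, origin = gor))
  if (kind == "affine") {
    A <- params$A
    if (is.null(A)) A <- matrix(0, 3, 3)
    off <- if (is.null(params$offset)) c(0, 0, 0) else params$offset
    dj <- det(diag(3) + A)
    if (dj <= 0)
      stop("non-physical affine deformation: det(I + A) = ", signif(dj, 4), " <= 0")
    u <- pts %*% t(A) + matrix(off, nrow(pts), 3, byrow = TRUE)
    f <- dvf_field(array(u, dim = c(gdim, 3)), gsp, gor)
    attr(f, "jacobian_fun") <- function(x, y, z) rep(dj, length(x))
    return(f)
  }
  if (kind == "gravity_gradient") {
    dir <- params$direction / sqrt(sum(params$direction^2))
    base <- if (is.null(params$base)) 0 else params$base
    slope <- if (is.null(params$slope)) 0 else params$slope
    ctr <- if (is.null(params$center)) gor + (gdim - 1) * gsp / 2 else params$center
    s <- (pts[, 1] - ctr[1]) * dir[1] + (pts[, 2] - ctr[2]) * dir[2] +
         (pts[, 3] - ctr[3]) * dir[3]
    # u = dir (base s + slope s^2 / 2): rank-one gradient, J = 1 + base + slope s
    if (min(1 + base + slope * range(s)) <= 0)
      stop("non-physical gradient deformation: Jacobian <= 0 inside the grid")
    amp <- base * s + slope * s^2 / 2
    u <- cbind(dir[1] * amp, dir[2] * amp, dir[3] * amp)
    f <- dvf_field(array(u, dim = c(gdim, 3)), gsp, gor)
    attr(f, "jacobian_fun") <- function(x, y, z) {
      sv <- (x - ctr[1]) * dir[1] + (y - ctr[2]) * dir[2] + (z - ctr[3]) * dir[3]
      1 + base + slope * sv
    }
    return(f)
  }
  # smooth_random: seeded Gaussian coefficients on a cubic B-spline grid
  amp <- params$amplitude_mm
  csp <- params$control_spacing_mm
  if (is.null(amp) || is.null(csp)) stop("smooth_random needs amplitude_mm and control_spacing_mm")
  wts <- lapply(1:3, function(k) bspline_axis_weights(gdim[k], gsp[k], gor[k], csp))
  ncp <- vapply(wts, `[[`, integer(1), "ncp")
  coef <- with_local_seed(if (is.null(params$seed)) 1L else params$seed,
                          array(stats::rnorm(prod(ncp) * 3, sd = amp), dim = c(ncp, 3)))
  u <- cpp_ffd_dense(coef, ncp, wts[[1]]$i0, wts[[1]]$w, wts[[2]]$i0, wts[[2]]$w,
                     wts[[3]]$i0, wts[[3]]$w)
  dvf_field(array(u, dim = c(gdim, 3)), gsp, gor)
}

#' Write a phantom pair to a directory
#'
#' Writes exhale/inhale volumes and masks as NIfTI-1, the ground-truth DVF as
#' 4D NIfTI, and the full phantom specification as a JSON sidecar.
#'
#' @param pair a \code{phantom_pair}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$exhale, file.path(dir, "exhale.nii.gz"))
  write_volume(pair$inhale, file.path(dir, "inhale.nii.gz"))
  write_dvf(pair$truth_dvf, file.path(dir, "truth_dvf.nii.gz"))
  write_volume(pair$truth_lungs, file.path(dir, "truth_lungs.nii.gz"))
  write_volume(pair$truth_lungs_inhale, file.path(dir, "truth_lungs_inhale.nii.gz"))
  spec <- pair$spec
  class(spec) <- NULL
  jsonlite::write_json(spec, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
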