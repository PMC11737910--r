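# Per-voxel cubic B-spline support weights along one axis. Control points sit
# at x0 + j * cspacing (j = 0..ncp-1); by default x0 = origin - cspacing and
# ncp covers the axis, so every voxel has its full 4-point support strictly
# inside the control grid. A shared lattice (x0, ncp) may be supplied so that
# several sampling grids address the same control points.
bspline_axis_weights <- function(n, spacing, origin, cspacing,
                                 x0 = NULL, ncp = NULL) {
  pos <- axis_coords(n, spacing, origin)
  if (is.null(x0)) x0 <- origin - cspacing
  s <- (pos - x0) / cspacing
  i <- floor(s)
  t <- s - i
  if (is.null(ncp)) ncp <- as.integer(floor(max(s)) + 3)
  if (min(i) < 1L || max(i) + 2L > ncp - 1L)
    stop("sampling grid extends beyond the B-spline control lattice")
  W <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  list(i0 = as.integer(i - 1), w = W, ncp = as.integer(ncp),
       origin = x0, spacing = cspacing)
}

#' Configure B-spline deformable registration
#'
#' Settings for multi-resolution free-form deformation with the expiration
#' phase as the fixed reference. All numeric defaults are package choices for
#' thoracic CT at around 2 mm voxels.
#'
#' @param pyramid_levels number of resolution levels; by default images are
#'   downsampled by 2^(levels - l) at level l (default 3: x4, x2, x1).
#' @param pyramid_factors optional integer vector of per-level downsampling
#'   factors (length \code{pyramid_levels}, non-increasing). Repeating a
#'   factor gives scale-space continuation: the same resolution is revisited
#'   with lighter smoothing, which widens the attraction basins for large
#'   displacements before refining.
#' @param control_spacing_mm B-spline knot spacing per level in mm, coarse to
#'   fine (length \code{pyramid_levels}; default 32, 16, 8).
#' @param metric similarity metric: \code{"ssd"} (mean squared HU difference,
#'   the mono-modal CT default) or \code{"ncc"} (one minus normalised cross
#'   correlation, robust to the global density dilution of an inhale phase).
#' @param bending_weight nonnegative weight of the bending-energy penalty on
#'   the control grid (default 0.01 for ncc-scaled metrics; the SSD metric is
#'   internally scaled so the same weight applies).
#' @param max_iterations maximum accepted gradient steps per level.
#' @param convergence_tol stop a level when the relative metric decrease
#'   falls below this for two consecutive accepted steps.
#' @param interpolation interpolation for the final warp: "linear" or "cubic".
#' @param init initialisation: \code{"block_match"} (default) seeds the
#'   control lattice from two-pass exhaustive block matching (wide search at
#'   half resolution, then a narrow residual search at full resolution
#'   against the warped moving image), which is immune to the local minima
#'   that trap gradient descent on large displacements; \code{"zero"} starts
#'   from the identity.
#' @param init_range_mm capture range of the first block-matching pass in mm.
#' @param sample_stride per-level integer stride thinning the fixed-image
#'   sample grid of the metric (default 2); the moving image keeps full
#'   resolution, so this trades metric sample density for speed.
#' @param smoothing_passes separable binomial smoothing passes applied to
#'   both images per pyramid level before matching (one value per level,
#'   coarse to fine, recycled from a scalar; default 6, 2, 1). Heavier
#'   smoothing at coarse levels widens the capture range for large
#'   displacements; a final light pass suppresses noise and keeps sampled
#'   image gradients consistent with the interpolator.
#' @param weight_band_hu fixed-image HU band treated as lung parenchyma for
#'   metric weighting (default -950 to -350).
#' @param background_weight relative metric weight of voxels outside the
#'   parenchyma band (default 0.1). Down-weighting the very strong
#'   body/mediastinum edges stops them from dominating the cost at smoothed
#'   pyramid levels, where blurred-edge mismatch otherwise biases the
#'   interior field; 1 restores the unweighted metric.
#' @param fold_check warn if the recovered field has Jacobian <= 0.05 anywhere.
#' @return A \code{registration_config} list.
#' @export
registration_config <- function(pyramid_levels = 2L,
                                pyramid_factors = c(2L, 1L),
                                control_spacing_mm = 12,
                                metric = c("ssd", "ncc"),
                                bending_weight = c(0.02, 0.01),
                                max_iterations = 150L,
                                convergence_tol = 1e-9,
                                interpolation = c("linear", "cubic"),
                                smoothing_passes = NULL,
                                init = c("block_match", "zero"),
                                init_range_mm = 32,
                                sample_stride = 2L,
                                weight_band_hu = c(-950, -350),
                                background_weight = 0.1,
                                fold_check = TRUE) {
  metric <- match.arg(metric)
  init <- match.arg(init)
  interpolation <- match.arg(interpolation)
  pyramid_levels <- as.integer(pyramid_levels)
  if (pyramid_levels < 1L) stop("'pyramid_levels' must be >= 1")
  if (is.null(pyramid_factors))
    pyramid_factors <- 2^(rev(seq_len(pyramid_levels)) - 1)
  pyramid_factors <- as.integer(pyramid_factors)
  if (length(pyramid_factors) != pyramid_levels || any(pyramid_factors < 1L) ||
      is.unsorted(rev(pyramid_factors)))
    stop("'pyramid_factors' must be ", pyramid_levels,
         " non-increasing positive integers")
  control_spacing_mm <- rep_len(as.numeric(control_spacing_mm), pyramid_levels)
  if (any(bending_weight < 0)) stop("'bending_weight' must be >= 0")
  if (is.null(smoothing_passes))
    smoothing_passes <- rev(seq_len(pyramid_levels)) - 1L   # e.g. 1, 0
  smoothing_passes <- rep_len(as.integer(smoothing_passes), pyramid_levels)
  structure(list(pyramid_levels = pyramid_levels,
                 pyramid_factors = pyramid_factors,
                 control_spacing_mm = as.numeric(control_spacing_mm),
                 metric = metric, bending_weight = bending_weight,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 interpolation = interpolation,
                 smoothing_passes = smoothing_passes,
                 init = init, init_range_mm = init_range_mm,
                 sample_stride = rep_len(as.integer(sample_stride), pyramid_levels),
                 weight_band_hu = as.numeric(weight_band_hu),
                 background_weight = background_weight,
                 fold_check = isTRUE(fold_check)),
            class = "registration_config")
}

# point subsampling of the voxel grid by an integer stride: keeps every
# stride-th voxel value (no averaging), so the result is the exact image
# restricted to a sparser sample grid
thin_volume <- function(v, s) {
  if (s == 1L) return(v)
  d <- dim(v$data)
  image_volume(v$data[seq.int(1L, d[1], s), seq.int(1L, d[2], s),
                      seq.int(1L, d[3], s), drop = FALSE],
               v$spacing * s, v$origin)
}

# block-mean downsampling by integer factor f (pad by edge replication)
downsample_volume <- function(v, f) {
  if (f == 1L) return(v)
  d <- dim(v$data)
  nd <- ceiling(d / f)
  idx <- lapply(1:3, function(k) pmin(rep(seq_len(d[k]), length.out = nd[k] * f), d[k]))
  # gather padded array then block average
  a <- v$data[idx[[1]], idx[[2]], idx[[3]]]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  image_volume(out, v$spacing * f, v$origin + (f - 1) / 2 * v$spacing)
}

# central-difference gradient volumes (per mm) of a volume, one-sided at edges
gradient_volumes <- function(v) {
  lapply(1:3, function(ax) diff_axis(v$data, ax, v$spacing[ax]))
}

# separable [1,2,1]/4 binomial smoothing, edge-replicated; 'passes' times
smooth3 <- function(arr, passes = 1L) {
  d <- dim(arr)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 3L) next
      sl <- function(w) switch(ax, arr[w, , , drop = FALSE],
                               arr[, w, , drop = FALSE], arr[, , w, drop = FALSE])
      arr <- (sl(c(1, 1:(n - 1))) + 2 * arr + sl(c(2:n, n))) / 4
      dim(arr) <- d
    }
  }
  arr
}

# d(arr)/d(axis) with central differences inside, one-sided at the borders
diff_axis <- function(arr, axis, spacing) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3L) stop("degenerate grid: axis ", axis, " has fewer than 3 voxels")
  ip <- c(2:n, n)
  im <- c(1, 1:(n - 1))
  den <- rep(2 * spacing, n)
  den[1] <- spacing; den[n] <- spacing
  idx <- function(w) switch(axis, arr[w, , , drop = FALSE],
                            arr[, w, , drop = FALSE], arr[, , w, drop = FALSE])
  out <- (idx(ip) - idx(im)) / rep(den, each = prod(d[seq_len(axis - 1)]))
  dim(out) <- d
  out
}

# resample one dvf-like 4D array onto a new grid (linear, zero fill)
resample_field <- function(field, spacing, origin, new_geom) {
  pts <- grid_points(new_geom)
  d <- dim(field)
  nd <- grid_dim(new_geom)
  out <- array(0, dim = c(nd, 3))
  for (c in 1:3)
    out[, , , c] <- cpp_sample3(field[, , , c], d[1:3], spacing, origin, pts, 0L, 0)
  out
}

# Bending penalty on the control-coefficient grid: mean squared second
# difference of the coefficients (mm^2 of curvature per control cell). Using
# coefficient-space curvature makes the penalty scale the same way at every
# pyramid level, since knot spacing and expected displacement both halve.
coef_bending <- function(coef, cspacing) {
  d <- dim(coef)
  nrm <- 1 / (3 * prod(d[1:3]))
  e <- 0
  grad <- array(0, dim = d)
  for (comp in 1:3) {
    a <- coef[, , , comp]
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 3) next
      lap <- second_diff(a, ax)
      e <- e + sum(lap^2) * nrm
      grad[, , , comp] <- grad[, , , comp] + 2 * nrm * second_diff_adj(lap, ax)
    }
  }
  list(value = e, grad = grad)
}

second_diff <- function(a, ax) {
  d <- dim(a)
  n <- d[ax]
  sl <- function(w) switch(ax, a[w, , , drop = FALSE], a[, w, , drop = FALSE],
                           a[, , w, drop = FALSE])
  out <- sl(3:n) - 2 * sl(2:(n - 1)) + sl(1:(n - 2))
  out
}

second_diff_adj <- function(v, ax) {
  # adjoint of second_diff: scatter [1, -2, 1] back to full size
  dv <- dim(v)
  d <- dv; d[ax] <- d[ax] + 2
  out <- array(0, dim = d)
  add <- function(out, w, val) {
    switch(ax,
           { out[w, , ] <- out[w, , ] + val; out },
           { out[, w, ] <- out[, w, ] + val; out },
           { out[, , w] <- out[, , w] + val; out })
  }
  n <- d[ax]
  out <- add(out, 1:(n - 2), v)
  out <- add(out, 2:(n - 1), -2 * v)
  out <- add(out, 3:n, v)
  out
}

# Initial control coefficients from exhaustive block matching at half
# resolution. Every stride-grid node with enough local contrast is matched by
# full integer search (plus parabolic sub-voxel refinement), outliers are
# removed by comparison with the median of neighbouring nodes, and the node
# displacements are fitted to the control lattice by Gaussian-weighted
# averaging. The exhaustive search gives a capture range limited only by
# 'range_mm', independent of any local-minimum structure.
block_match_coef <- function(fixed, moving, csp, lat_x0, ncp,
                             range_mm = 32, block_half = 3L, stride = 2L,
                             min_sd = 15, down = 2L) {
  fx <- downsample_volume(fixed, down)
  mv <- downsample_volume(moving, down)
  fx$data <- smooth3(fx$data, 1L)
  mv$data <- smooth3(mv$data, 1L)
  d <- grid_dim(fx)
  range_vox <- as.integer(ceiling(range_mm / max(fx$spacing)))
  bm <- cpp_block_match(fx$data, mv$data, d, stride, block_half,
                        range_vox, min_sd)
  coef <- array(0, dim = c(ncp, 3))
  if (nrow(bm) < 8L) return(coef)
  # arrange nodes on their own regular grid for neighbourhood filtering
  margin <- block_half + range_vox
  gi <- (bm[, 1] - margin) / stride + 1
  gj <- (bm[, 2] - margin) / stride + 1
  gk <- (bm[, 3] - margin) / stride + 1
  gd <- c(max(gi), max(gj), max(gk))
  disp <- array(NA_real_, dim = c(gd, 3))
  for (c in 1:3)
    disp[cbind(gi, gj, gk, c)] <- bm[, 3 + c] * fx$spacing[c]
  # drop nodes far from the median of their 3x3x3 node neighbourhood
  ok <- !is.na(disp[, , , 1])
  keep <- rep(TRUE, nrow(bm))
  for (r in seq_len(nrow(bm))) {
    ii <- max(1, gi[r] - 1):min(gd[1], gi[r] + 1)
    jj <- max(1, gj[r] - 1):min(gd[2], gj[r] + 1)
    kk <- max(1, gk[r] - 1):min(gd[3], gk[r] + 1)
    dev <- 0
    for (c in 1:3) {
      med <- stats::median(disp[ii, jj, kk, c], na.rm = TRUE)
      dev <- max(dev, abs(disp[gi[r], gj[r], gk[r], c] - med))
    }
    if (dev > 6) keep[r] <- FALSE
  }
  bm <- bm[keep, , drop = FALSE]
  if (nrow(bm) < 8L) return(coef)
  pos <- sweep(bm[, 1:3, drop = FALSE], 2, fx$spacing, "*") +
         matrix(fx$origin, nrow(bm), 3, byrow = TRUE)
  um <- sweep(bm[, 4:6, drop = FALSE], 2, fx$spacing, "*")
  # Gaussian-weighted average of node displacements at each control point;
  # individual node errors are close to random, so local averaging at the
  # knot-spacing scale suppresses them without overfitting
  h2 <- 2 * csp^2
  cxs <- lat_x0[1] + (seq_len(ncp[1]) - 1) * csp
  cys <- lat_x0[2] + (seq_len(ncp[2]) - 1) * csp
  czs <- lat_x0[3] + (seq_len(ncp[3]) - 1) * csp
  wx <- exp(-outer(cxs, pos[, 1], "-")^2 / h2)
  wy <- exp(-outer(cys, pos[, 2], "-")^2 / h2)
  wz <- exp(-outer(czs, pos[, 3], "-")^2 / h2)
  for (c in 1:3) {
    num <- array(0, dim = ncp)
    den <- array(0, dim = ncp)
    for (n in seq_len(nrow(bm))) {
      w3 <- outer(outer(wx[, n], wy[, n]), wz[, n])
      num <- num + w3 * um[n, c]
      den <- den + w3
    }
    coef[, , , c] <- ifelse(den > 1e-3, num / pmax(den, 1e-3), 0)
  }
  coef
}

# Two-scale block-matching initialisation: a wide-range search at half
# resolution captures the bulk displacement, then the moving image is warped
# by that estimate and a narrow-range full-resolution search measures the
# residual, which is added to the lattice coefficients. Both passes are
# exhaustive searches, so the initialisation cannot be caught in the local
# minima that trap gradient-based refinement of large displacements.
block_match_field <- function(fixed, moving, csp, lat_x0, ncp, range_mm = 32) {
  coef <- block_match_coef(fixed, moving, csp, lat_x0, ncp,
                           range_mm = range_mm, down = 2L)
  fdim <- grid_dim(fixed)
  wts <- lapply(1:3, function(k)
    bspline_axis_weights(fdim[k], fixed$spacing[k], fixed$origin[k], csp,
                         x0 = lat_x0[k], ncp = ncp[k]))
  u <- cpp_ffd_dense(coef, ncp, wts[[1]]$i0, wts[[1]]$w, wts[[2]]$i0,
                     wts[[2]]$w, wts[[3]]$i0, wts[[3]]$w)
  warped <- warp(moving, dvf_field(array(u, dim = c(fdim, 3)),
                                   fixed$spacing, fixed$origin), "cubic")
  coef + block_match_coef(fixed, warped, csp, lat_x0, ncp,
                          range_mm = 8, block_half = 4L, stride = 2L,
                          min_sd = 15, down = 1L)
}

#' Register inhale to exhale by B-spline free-form deformation
#'
#' Estimates the dense displacement field u on the fixed (exhale) grid such
#' that moving(x + u(x)) matches fixed(x), by multi-resolution cubic B-spline
#' free-form deformation with a bending-energy penalty, optimised by
#' deterministic gradient descent with backtracking line search. No random
#' initialisation is used: identical inputs give identical fields.
#'
#' @param fixed the reference \code{ctvi_volume} (expiration phase).
#' @param moving the \code{ctvi_volume} to be deformed (inspiration phase).
#' @param config a \code{\link{registration_config}}.
#' @param verbose print per-level progress.
#' @return A \code{\link{dvf_field}} on the fixed grid with attributes
#'   \code{"metric"} (final metric value) and \code{"iterations"} (accepted
#'   steps per level) and \code{"metric_trace"} (per-level metric histories).
#' @export
register_bspline <- function(fixed, moving, config = registration_config(),
                             verbose = FALSE) {
  stopifnot(inherits(fixed, "ctvi_volume"), inherits(moving, "ctvi_volume"))
  # fields of view must overlap
  lo_f <- fixed$origin; hi_f <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing
  lo_m <- moving$origin; hi_m <- moving$origin + (grid_dim(moving) - 1) * moving$spacing
  if (any(hi_m < lo_f) || any(lo_m > hi_f))
    stop("fixed and moving fields of view do not overlap")
  nlev <- config$pyramid_levels
  metric_code <- if (config$metric == "ssd") 0L else 1L
  # One control lattice, shared by every pyramid level: coefficients carry
  # over exactly between levels (same-lattice B-splines add), and the bending
  # penalty always acts on the TOTAL field, not on a level's increment. The
  # margin keeps the block-centre shift of downsampled grids inside support.
  csp <- min(config$control_spacing_mm)
  margin <- csp + max(fixed$spacing) * max(config$pyramid_factors)
  lat_x0 <- fixed$origin - margin
  lat_hi <- fixed$origin + (grid_dim(fixed) - 1) * fixed$spacing + margin
  ncp <- as.integer(floor((lat_hi - lat_x0) / csp) + 3)
  lam_sched <- rep_len(config$bending_weight, nlev)
  coef <- if (config$init == "block_match" && all(grid_dim(fixed) >= 32L) &&
              same_geometry(fixed, moving))
    block_match_field(fixed, moving, csp, lat_x0, ncp,
                      range_mm = config$init_range_mm)
  else array(0, dim = c(ncp, 3))
  iters <- integer(nlev)
  traces <- vector("list", nlev)
  final_metric <- NA_real_
  for (lev in seq_len(nlev)) {
    f <- config$pyramid_factors[lev]
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    fx$data <- smooth3(fx$data, config$smoothing_passes[lev])
    mv$data <- smooth3(mv$data, config$smoothing_passes[lev])
    # thinning the fixed sample grid trades metric sample density for speed;
    # the moving image keeps its resolution
    fx <- thin_volume(fx, config$sample_stride[lev])
    fdim <- grid_dim(fx)
    wts <- lapply(1:3, function(k)
      bspline_axis_weights(fdim[k], fx$spacing[k], fx$origin[k], csp,
                           x0 = lat_x0[k], ncp = ncp[k]))
    vweight <- if (config$background_weight >= 1) numeric(0)
               else {
      inband <- fx$data >= config$weight_band_hu[1] &
                fx$data <= config$weight_band_hu[2]
      ifelse(inband, 1, config$background_weight)
    }
    # SSD is in HU^2; scale it so bending_weight acts on a O(1) metric
    mscale <- if (metric_code == 0L) 1 / (400^2) else 1
    lam <- lam_sched[lev]
    eval_mg <- function(cf, want_grad) {
      r <- cpp_metric_grad(fx$data, fdim, fx$spacing, fx$origin,
                           mv$data, grid_dim(mv), mv$spacing, mv$origin,
                           numeric(0), FALSE,
                           cf, ncp, wts[[1]]$i0, wts[[1]]$w,
                           wts[[2]]$i0, wts[[2]]$w, wts[[3]]$i0, wts[[3]]$w,
                           metric_code, -1000, want_grad, vweight)
      b <- if (lam > 0) coef_bending(cf, csp)
           else list(value = 0, grad = 0)
      list(value = r$value * mscale + lam * b$value,
           grad = if (want_grad) r$grad * mscale + lam * b$grad else NULL)
    }
    # limited-memory quasi-Newton on the control coefficients (deterministic;
    # analytic gradient); cache the last evaluation since L-BFGS-B requests
    # fn and gr at the same point
    cache <- new.env()
    cache$trace <- numeric(0)
    opt <- stats::optim(as.numeric(coef),
                        fn = function(par) {
                          v <- eval_mg(array(par, dim = c(ncp, 3)), FALSE)$value
                          cache$trace <- c(cache$trace,
                                           min(v, cache$trace[length(cache$trace)],
                                               na.rm = TRUE))
                          v
                        },
                        gr = function(par)
                          as.numeric(eval_mg(array(par, dim = c(ncp, 3)), TRUE)$grad),
                        method = "L-BFGS-B",
                        control = list(maxit = config$max_iterations,
                                       factr = config$convergence_tol /
                                               .Machine$double.eps))
    if (opt$convergence == 1L && verbose)
      message("level ", lev, ": iteration limit reached before convergence")
    coef <- array(opt$par, dim = c(ncp, 3))
    if (opt$value > cache$trace[1] + 1e-9)
      stop("registration diverged at pyramid level ", lev)
    iters[lev] <- opt$counts[["function"]]
    traces[[lev]] <- cache$trace
    final_metric <- opt$value
    if (verbose)
      message(sprintf("level %d (x%d, smoothing %d): %d evaluations, metric %.6g",
                      lev, f, config$smoothing_passes[lev], iters[lev], final_metric))
  }
  fdim_full <- grid_dim(fixed)
  wts_full <- lapply(1:3, function(k)
    bspline_axis_weights(fdim_full[k], fixed$spacing[k], fixed$origin[k], csp,
                         x0 = lat_x0[k], ncp = ncp[k]))
  u_total <- cpp_ffd_dense(coef, ncp, wts_full[[1]]$i0, wts_full[[1]]$w,
                           wts_full[[2]]$i0, wts_full[[2]]$w,
                           wts_full[[3]]$i0, wts_full[[3]]$w)
  out <- dvf_field(array(u_total, dim = c(fdim_full, 3)),
                   fixed$spacing, fixed$origin)
  if (config$fold_check) {
    jmin <- min(jacobian_map(out)$data)
    if (jmin <= 0.05)
      warning("recovered deformation is close to folding (min Jacobian ",
              signif(jmin, 3), ")")
  }
  attr(out, "metric") <- final_metric
  attr(out, "iterations") <- iters
  attr(out, "metric_trace") <- traces
  out
}

#' Warp a volume through a displacement field
#'
#' Samples \code{volume} at x + u(x) for every voxel x of the field's grid,
#' so that warping the inspiration image with the expiration-to-inspiration
#' field brings it into the expiration frame. Samples outside the volume take
#' ambient air HU (-1000) by default.
#'
#' @param volume a \code{ctvi_volume} to sample from.
#' @param dvf a \code{\link{dvf_field}} on the output grid.
#' @param interpolation "linear" or "cubic".
#' @param fill value for out-of-domain samples (default -1000).
#' @return A \code{ctvi_volume} on the field's grid.
#' @export
warp <- function(volume, dvf, interpolation = c("linear", "cubic"), fill = -1000) {
  stopifnot(inherits(volume, "ctvi_volume"), inherits(dvf, "ctvi_dvf"))
  interpolation <- match.arg(interpolation)
  pts <- grid_points(dvf)
  d <- grid_dim(dvf)
  nvox <- prod(d)
  uf <- dvf$field
  dim(uf) <- c(nvox, 3)
  out <- cpp_sample3(volume$data, grid_dim(volume), volume$spacing, volume$origin,
                     pts + uf, if (interpolation == "cubic") 1L else 0L, fill)
  image_volume(array(out, dim = d), dvf$spacing, dvf$origin)
}

#' Bending energy of a displacement field
#'
#' Sum over voxels of the squared second spatial derivatives of all three
#' displacement components (all nine second-derivative terms, mixed terms
#' counted twice), scaled by the voxel volume. Zero exactly for affine
#' fields; used as the smoothness penalty of the registration.
#'
#' @param dvf a \code{\link{dvf_field}}.
#' @return Nonnegative scalar (mm^3 x (1/mm)^2 units).
#' @export
bending_energy <- function(dvf) {
  stopifnot(inherits(dvf, "ctvi_dvf"))
  sp <- dvf$spacing
  vv <- prod(sp)
  e <- 0
  for (comp in 1:3) {
    a <- dvf$field[, , , comp]
    d1 <- lapply(1:3, function(ax) diff_axis(a, ax, sp[ax]))
    for (ax1 in 1:3) for (ax2 in ax1:3) {
      d2 <- diff_axis(d1[[ax1]], ax2, sp[ax2])
      w <- if (ax2 > ax1) 2 else 1
      e <- e + w * sum(d2^2)
    }
  }
  e * vv
}
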