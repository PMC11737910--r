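test_that("phantom generation is bit-reproducible for identical spec and seed", {
  a <- generate_phantom(small_spec(seed = 42))
  b <- generate_phantom(small_spec(seed = 42))
  expect_identical(a$exhale$data, b$exhale$data)
  expect_identical(a$inhale$data, b$inhale$data)
  expect_identical(a$truth_dvf$field, b$truth_dvf$field)
  c <- generate_phantom(small_spec(seed = 43))
  expect_false(identical(a$exhale$data, c$exhale$data))
})

test_that("no breathing means identical phases and unit Jacobian", {
  p <- generate_phantom(small_spec(global_expansion = 1.0, gravity_gradient = 0,
                                   diaphragm_gradient = 0, bulk_shift_mm = 0,
                                   noise_sd_hu = 0))
  expect_equal(max(abs(p$truth_dvf$field)), 0)
  expect_equal(p$inhale$data, p$exhale$data, tolerance = 1e-12)
  jm <- jacobian_map(p$truth_dvf)
  expect_true(all(jm$data == 1))
})

test_that("lung volume ratio reproduces the target mean expansion", {
  p <- cached_phantom()
  ratio <- lung_volume(p$truth_lungs_inhale) / lung_volume(p$truth_lungs)
  expect_equal(ratio, p$spec$global_expansion, tolerance = 0.02)
  expect_equal(p$mean_lung_jacobian, p$spec$global_expansion, tolerance = 0.02)
})

test_that("Jacobian integral over the exhale lungs matches the inhale lung volume", {
  p <- generate_phantom(small_spec(noise_sd_hu = 0))
  jm <- jacobian_map(p$truth_dvf)
  lun <- p$truth_lungs$data > 0
  vol_pred <- sum(jm$data[lun]) * prod(p$exhale$spacing) / 1000
  vol_inhale <- lung_volume(p$truth_lungs_inhale)
  expect_equal(vol_pred, vol_inhale, tolerance = 0.02)
})

test_that("the dependent lung side expands more in every position", {
  jm_half_means <- function(p) {
    jm <- jacobian_map(p$truth_dvf)
    lun <- p$truth_lungs$data > 0
    g <- p$gravity
    ax <- which(g != 0)
    d <- dim(jm$data)
    coord <- slice.index(jm$data, ax)
    dep <- if (g[ax] > 0) coord > (d[ax] + 1) / 2 else coord < (d[ax] + 1) / 2
    c(dependent = mean(jm$data[lun & dep]), other = mean(jm$data[lun & !dep]))
  }
  for (pos in c("supine", "prone", "right_lateral", "left_lateral")) {
    p <- generate_phantom(small_spec(position = pos))
    m <- jm_half_means(p)
    expect_gt(m["dependent"], m["other"])
  }
})

test_that("truth field is zero outside the body and the deformation does not fold", {
  p <- cached_phantom()
  outside <- p$exhale$data < -990 & p$truth_lungs$data == 0
  mag <- sqrt(p$truth_dvf$field[, , , 1]^2 + p$truth_dvf$field[, , , 2]^2 +
              p$truth_dvf$field[, , , 3]^2)
  # ambient air voxels: strictly zero motion (noise can blur the -990
  # threshold into the body edge, so allow the taper's vanishing tail)
  expect_lt(max(mag[outside]), 0.75)
  corner <- mag[1:3, 1:3, 1:3]
  expect_equal(max(corner), 0)
  jm <- jacobian_map(p$truth_dvf)
  expect_gt(min(jm$data), 0.05)
})

test_that("warping the inhale phase through the truth field recovers the exhale lungs", {
  p <- generate_phantom(small_spec(noise_sd_hu = 0, density_rescale = FALSE))
  w <- warp(p$inhale, p$truth_dvf)
  lun <- p$truth_lungs$data > 0
  # interior of the lungs (away from the sharp pleural boundary)
  er <- lun
  for (ax in 1:3) {
    n <- dim(er)[ax]
    sh <- function(a, w) switch(ax, a[w, , , drop = FALSE],
                                a[, w, , drop = FALSE], a[, , w, drop = FALSE])
    er <- er & sh(lun, pmax(1:n - 2, 1)) & sh(lun, pmin(1:n + 2, n))
  }
  mae <- mean(abs(w$data - p$exhale$data)[er])
  expect_lt(mae, 15)  # interpolation-level residual, far below texture contrast
})

test_that("mirroring the supine gravity axis yields the prone Jacobian map mirrored", {
  w <- c(0.2, 0.4, 0.4)
  sup <- generate_phantom(small_spec(position = "supine", noise_sd_hu = 0,
                                     axis_weights = w, bulk_shift_mm = 4))
  pro <- generate_phantom(small_spec(position = "prone", noise_sd_hu = 0,
                                     axis_weights = w, bulk_shift_mm = 4))
  js <- jacobian_map(sup$truth_dvf)$data
  jp <- jacobian_map(pro$truth_dvf)$data
  n <- dim(js)[2]
  expect_equal(jp, js[, n:1, ], tolerance = 1e-9)
})

test_that("phantom pair writes volumes, field, masks and a JSON sidecar", {
  p <- cached_phantom()
  dir <- tempfile("phantom_")
  write_phantom(p, dir)
  expect_true(all(file.exists(file.path(dir,
    c("exhale.nii.gz", "inhale.nii.gz", "truth_dvf.nii.gz",
      "truth_lungs.nii.gz", "phantom_spec.json")))))
  r <- read_volume(file.path(dir, "exhale.nii.gz"))
  expect_equal(r$data, p$exhale$data, tolerance = 1e-12)
  f <- read_dvf(file.path(dir, "truth_dvf.nii.gz"), reference = r)
  expect_equal(f$field, p$truth_dvf$field, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "phantom_spec.json"))
  expect_equal(js$position, p$spec$position)
  expect_equal(js$global_expansion, p$spec$global_expansion)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(global_expansion = -1), "global_expansion")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "grid_shape")
  expect_error(phantom_spec(gravity_gradient = 0.9), "gravity_gradient")
  expect_error(
    generate_phantom(small_spec(lung_geometry = list(center_offset_mm = 60,
                                                     semi_axes_mm = c(40, 60, 80)))),
    "inside the body")
})
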