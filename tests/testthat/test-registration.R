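# registration tests run on a 48^3 / 4 mm phantom to stay fast

test_that("self-registration returns a negligible field", {
  p <- cached_phantom()
  dvf <- suppressWarnings(register_bspline(p$exhale, p$exhale))
  expect_lt(max(abs(dvf$field)), 0.1 * p$exhale$spacing[1])
})

test_that("a known rigid translation is recovered", {
  p <- generate_phantom(small_spec(noise_sd_hu = 0))
  shift <- analytic_dvf("affine", list(A = matrix(0, 3, 3), offset = c(-4, 0, 0)),
                        p$exhale)
  moving <- warp(p$exhale, shift)   # the scene moved by +4 mm along x
  dvf <- suppressWarnings(register_bspline(p$exhale, moving))
  body <- p$exhale$data > -900
  rec <- c(mean(dvf$field[, , , 1][body]), mean(dvf$field[, , , 2][body]),
           mean(dvf$field[, , , 3][body]))
  expect_equal(rec, c(4, 0, 0), tolerance = 0.5)
})

test_that("registration is deterministic", {
  p <- cached_phantom()
  a <- suppressWarnings(register_bspline(p$exhale, p$inhale))
  b <- suppressWarnings(register_bspline(p$exhale, p$inhale))
  expect_identical(a$field, b$field)
})

test_that("recorded metric is non-increasing over accepted iterates", {
  p <- cached_phantom()
  dvf <- suppressWarnings(register_bspline(p$exhale, p$inhale))
  for (tr in attr(dvf, "metric_trace"))
    expect_true(all(diff(tr) <= 1e-12))
})

test_that("phantom deformation is recovered to sub-voxel accuracy", {
  p <- cached_phantom()
  dvf <- suppressWarnings(register_bspline(p$exhale, p$inhale))
  err <- dvf$field - p$truth_dvf$field
  epe <- sqrt(err[, , , 1]^2 + err[, , , 2]^2 + err[, , , 3]^2)
  lun <- p$truth_lungs$data > 0
  expect_lt(mean(epe[lun]), 0.6 * p$exhale$spacing[1])
  jest <- jacobian_map(dvf)
  jtru <- jacobian_map(p$truth_dvf)
  rho <- stats::cor(jest$data[lun], jtru$data[lun], method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("non-overlapping fields of view are rejected", {
  a <- image_volume(array(0, dim = c(8, 8, 8)), c(2, 2, 2), c(0, 0, 0))
  b <- image_volume(array(0, dim = c(8, 8, 8)), c(2, 2, 2), c(1000, 0, 0))
  expect_error(register_bspline(a, b), "overlap")
})

test_that("warp handles the zero field, pure shifts and boundary fill", {
  p <- cached_phantom()
  z <- dvf_field(array(0, dim = c(dim(p$exhale$data), 3)),
                 p$exhale$spacing, p$exhale$origin)
  expect_equal(warp(p$exhale, z)$data, p$exhale$data, tolerance = 1e-12)

  one_voxel <- p$exhale$spacing[1]
  s <- z; s$field[, , , 1] <- one_voxel
  w <- warp(p$exhale, s)
  d <- dim(p$exhale$data)
  expect_equal(w$data[1:(d[1] - 1), , ], p$exhale$data[2:d[1], , ],
               tolerance = 1e-12)
  expect_true(all(w$data[d[1], , ] == -1000))
})

test_that("warp rejects geometry mismatch between field and output grid", {
  v <- image_volume(array(0, dim = c(8, 8, 8)), c(2, 2, 2))
  f <- dvf_field(array(0, dim = c(8, 8, 8, 3)), c(2, 2, 2))
  expect_silent(warp(v, f))
  # a field is usable on any sampling volume; but a malformed field is not
  expect_error(dvf_field(array(0, dim = c(8, 8, 8, 2)), c(2, 2, 2)),
               "3 components")
})

test_that("bending energy is zero for affine fields and matches a brute-force sum", {
  grid <- list(dim = c(10L, 10L, 10L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  z <- analytic_dvf("affine", list(A = matrix(0, 3, 3)), grid)
  expect_equal(bending_energy(z), 0)
  aff <- analytic_dvf("affine",
                      list(A = matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0, 0, 0.02, 0.04), 3, 3),
                           offset = c(1, -2, 3)), grid)
  expect_equal(bending_energy(aff), 0, tolerance = 1e-18)

  f <- analytic_dvf("smooth_random",
                    list(amplitude_mm = 2, control_spacing_mm = 8, seed = 3), grid)
  # independent brute-force: loop over components and derivative pairs
  sp <- f$spacing
  acc <- 0
  for (comp in 1:3) {
    a <- f$field[, , , comp]
    for (ax1 in 1:3) for (ax2 in 1:3) {
      d1 <- bhctvi:::diff_axis(a, ax1, sp[ax1])
      d2 <- bhctvi:::diff_axis(d1, ax2, sp[ax2])
      acc <- acc + sum(d2^2)
    }
  }
  expect_equal(bending_energy(f), acc * prod(sp), tolerance = 1e-8)
})
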