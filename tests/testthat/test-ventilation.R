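test_that("zero displacement gives a Jacobian of exactly 1 everywhere", {
  grid <- list(dim = c(12L, 12L, 12L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  f <- analytic_dvf("affine", list(A = matrix(0, 3, 3)), grid)
  jm <- jacobian_map(f)
  expect_true(all(jm$data == 1))
})

test_that("affine fields give det(I + A) at interior voxels", {
  grid <- list(dim = c(14L, 12L, 10L), spacing = c(2, 1.5, 2.5), origin = c(0, 0, 0))
  # the diagonal stretch quoted with the determinant metric: 1.1 * 1.2 * 1.0
  A <- diag(c(0.1, 0.2, 0))
  jm <- jacobian_map(analytic_dvf("affine", list(A = A), grid))
  expect_equal(max(abs(jm$data - 1.32)), 0, tolerance = 1e-10)

  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rnorm(9, sd = 0.08), 3, 3)
    if (det(diag(3) + A) <= 0) next
    jm <- jacobian_map(analytic_dvf("affine", list(A = A), grid))
    interior <- jm$data[2:13, 2:11, 2:9]
    expect_equal(max(abs(interior - det(diag(3) + A))), 0, tolerance = 1e-6)
  }
})

test_that("singular affine expansion is rejected as non-physical", {
  grid <- list(dim = c(8L, 8L, 8L), spacing = c(1, 1, 1))
  expect_error(analytic_dvf("affine", list(A = diag(c(-1, 0, 0))), grid),
               "non-physical")
})

test_that("smooth random field matches an independent per-voxel determinant oracle", {
  grid <- list(dim = c(20L, 18L, 16L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  f <- analytic_dvf("smooth_random",
                    list(amplitude_mm = 3, control_spacing_mm = 12, seed = 7), grid)
  jm <- jacobian_map(f)
  set.seed(7)
  for (t in 1:20) {
    i <- sample(2:19, 1); j <- sample(2:17, 1); k <- sample(2:15, 1)
    expect_equal(jm$data[i, j, k],
                 fd_jacobian_at(f$field, f$spacing, i, j, k),
                 tolerance = 1e-10)
  }
})

test_that("gravity-gradient field matches its closed-form Jacobian", {
  grid <- list(dim = c(16L, 16L, 16L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  f <- analytic_dvf("gravity_gradient",
                    list(direction = c(0, 1, 0), base = 0.1, slope = 0.005), grid)
  jfun <- attr(f, "jacobian_fun")
  jm <- jacobian_map(f)
  ys <- (seq_len(16) - 1) * 2
  expected <- jfun(rep(15, 16), ys, rep(15, 16))
  got <- jm$data[8, , 8]
  expect_equal(got[2:15], expected[2:15], tolerance = 1e-10)
})

test_that("jacobian_map rejects degenerate grids", {
  f <- dvf_field(array(0, dim = c(2, 8, 8, 3)), c(1, 1, 1))
  expect_error(jacobian_map(f), "degenerate")
})

test_that("percentile ranks follow the mid-rank formula", {
  jm <- image_volume(array(c(1.0, 1.1, 1.2, 1.3, rep(9, 4)), dim = c(2, 2, 2)))
  mask <- array(c(rep(TRUE, 4), rep(FALSE, 4)), dim = c(2, 2, 2))
  pm <- percentile_map(jm, mask)
  expect_equal(as.numeric(pm$data[1:4]), c(12.5, 37.5, 62.5, 87.5))
  expect_true(all(is.na(pm$data[5:8])))

  # constant values: all mid-ranks are 50
  jc <- image_volume(array(2, dim = c(2, 2, 2)))
  pc <- percentile_map(jc, mask)
  expect_true(all(pc$data[1:4] == 50))
})

test_that("percentile ranks are invariant under strictly monotone transforms", {
  set.seed(3)
  v <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  mask <- array(TRUE, dim = c(4, 4, 4))
  p1 <- percentile_map(image_volume(v), mask)
  p2 <- percentile_map(image_volume(exp(3 * v) + 5), mask)
  expect_equal(p1$data, p2$data)
})

test_that("percentile_map requires a nonempty mask", {
  jm <- image_volume(array(1, dim = c(3, 3, 3)))
  expect_error(percentile_map(jm, array(FALSE, dim = c(3, 3, 3))), "empty mask")
})

test_that("functional mask flags the top quartile at the default threshold", {
  set.seed(11)
  d <- c(10L, 10L, 10L)
  v <- array(sample(seq_len(1000)), dim = d)  # all distinct
  mask <- array(TRUE, dim = d)
  pm <- percentile_map(image_volume(v), mask)
  hf <- functional_mask(pm, 75)
  expect_equal(sum(hf$data), 250)
  # flagged voxels are exactly the 250 largest values
  expect_true(min(v[hf$data == 1]) > max(v[hf$data == 0]))

  # count is non-increasing in the threshold
  counts <- vapply(c(10, 25, 50, 75, 90, 99),
                   function(th) sum(functional_mask(pm, th)$data), 0)
  expect_true(all(diff(counts) <= 0))

  # degenerate constant map: rank 50 everywhere, nothing above 75
  pc <- percentile_map(image_volume(array(1, dim = d)), mask)
  expect_equal(sum(functional_mask(pc, 75)$data), 0)
})

test_that("jacobian map is unchanged by mirroring the field and grid", {
  grid <- list(dim = c(12L, 12L, 12L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  f <- analytic_dvf("smooth_random",
                    list(amplitude_mm = 2, control_spacing_mm = 10, seed = 5), grid)
  jm <- jacobian_map(f)
  # reflect along x: reverse the axis and negate the x component
  rev_field <- f$field[12:1, , , ]
  rev_field[, , , 1] <- -rev_field[, , , 1]
  jr <- jacobian_map(dvf_field(rev_field, f$spacing, f$origin))
  expect_equal(jr$data[12:1, , ], jm$data, tolerance = 1e-12)
})
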