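make_uniform_dvf <- function(u, d = c(8L, 8L, 8L)) {
  f <- array(0, dim = c(d, 3))
  for (c in 1:3) f[, , , c] <- u[c]
  dvf_field(f, c(2, 2, 2))
}

test_that("gravity alignment and parallelism behave on canonical fields", {
  mask <- array(TRUE, dim = c(8, 8, 8))
  g <- c(0, 1, 0)
  down <- region_vector_summary(make_uniform_dvf(c(0, 5, 0)), mask, g)
  expect_equal(down$gravity_alignment, 1)
  expect_equal(down$ground_parallelism, 0)

  caudal <- region_vector_summary(make_uniform_dvf(c(0, 0, -5)), mask, g)
  expect_equal(caudal$gravity_alignment, 0)
  expect_equal(caudal$ground_parallelism, 1)
  expect_equal(caudal$mean_magnitude_mm, 5)
})

test_that("alignment is the magnitude-weighted mean cosine", {
  d <- c(8L, 8L, 8L)
  f <- array(0, dim = c(d, 3))
  half <- slice.index(array(0, d), 1) <= 4
  f[, , , 2][half] <- 3    # half the voxels move (0, 3, 0)
  f[, , , 3][!half] <- 4   # the rest move (0, 0, 4)
  s <- region_vector_summary(dvf_field(f, c(2, 2, 2)), array(TRUE, d), c(0, 1, 0))
  expect_equal(s$gravity_alignment, 3 / 7)   # (3*1 + 4*0) / (3 + 4)
})

test_that("negating gravity flips alignment but not parallelism", {
  grid <- list(dim = c(10L, 10L, 10L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  f <- analytic_dvf("smooth_random",
                    list(amplitude_mm = 3, control_spacing_mm = 10, seed = 2), grid)
  mask <- array(TRUE, dim = c(10, 10, 10))
  a <- region_vector_summary(f, mask, c(0, 1, 0))
  b <- region_vector_summary(f, mask, c(0, -1, 0))
  expect_equal(a$gravity_alignment, -b$gravity_alignment)
  expect_equal(a$ground_parallelism, b$ground_parallelism)
})

test_that("sub-floor displacements leave orientation statistics undefined", {
  mask <- array(TRUE, dim = c(8, 8, 8))
  tiny <- region_vector_summary(make_uniform_dvf(c(0.1, 0.1, 0)), mask, c(0, 1, 0))
  expect_true(is.na(tiny$gravity_alignment))
  expect_true(is.na(tiny$ground_parallelism))
  expect_equal(tiny$n_oriented, 0)
  expect_error(region_vector_summary(make_uniform_dvf(c(1, 0, 0)), mask, c(0, 0, 0)),
               "nonzero")
  expect_error(region_vector_summary(make_uniform_dvf(c(1, 0, 0)),
                                     array(FALSE, dim = c(8, 8, 8)), c(0, 1, 0)),
               "empty region")
})

test_that("phantom truth fields show the position-specific orientation signatures", {
  sup <- cached_phantom()
  s <- region_vector_summary(sup$truth_dvf, sup$truth_lungs$data > 0, sup$gravity)
  expect_lt(s$gravity_alignment, -0.5)   # supine: motion opposes gravity

  pro <- generate_phantom(small_spec(position = "prone"))
  pr <- region_vector_summary(pro$truth_dvf, pro$truth_lungs$data > 0, pro$gravity)
  expect_gt(pr$ground_parallelism, 0.9)  # prone: cranio-caudal, ground-parallel
  expect_lt(pr$mean_uz, 0)               # directed head to feet
})

test_that("arrow export subsamples deterministically on the stride grid", {
  p <- cached_phantom()
  mask <- p$truth_lungs$data > 0
  a <- export_arrows(p$truth_dvf, mask, stride = 4)
  d <- dim(mask)
  sel <- array(FALSE, dim = d)
  sel[seq(1, d[1], 4), seq(1, d[2], 4), seq(1, d[3], 4)] <- TRUE
  expect_equal(nrow(a), sum(sel & mask))
  expect_equal(a$magnitude_mm, sqrt(a$ux^2 + a$uy^2 + a$uz^2))
  b <- export_arrows(p$truth_dvf, mask, stride = 4)
  expect_identical(a, b)
  z <- dvf_field(array(0, dim = c(d, 3)), p$truth_dvf$spacing)
  expect_true(all(export_arrows(z, mask, stride = 8)$magnitude_mm == 0))
})
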