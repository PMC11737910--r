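test_that("lung segmentation recovers the phantom lungs with high Dice", {
  p <- cached_phantom()
  seg <- segment_lungs(p$exhale)
  for (lab in 1:2)
    expect_gt(dice(seg$data == lab, p$truth_lungs$data == lab), 0.95)
})

test_that("segmentation fails cleanly without a body", {
  v <- image_volume(array(-1000, dim = c(24, 24, 24)), c(4, 4, 4))
  expect_error(segment_lungs(v), "segmentation failed")
})

test_that("a single-lung phantom yields one labelled lung and no error", {
  p <- cached_phantom()
  ct <- p$exhale
  # fill the left lung (x above the midline) with soft tissue
  left <- p$truth_lungs$data == 1
  ct$data[left] <- 40
  seg <- segment_lungs(ct)
  expect_equal(sum(seg$data == 1), 0)
  expect_gt(dice(seg$data == 2, p$truth_lungs$data == 2), 0.95)
})

test_that("lung volume converts voxel counts with the voxel volume", {
  m <- array(0L, dim = c(20, 10, 10))
  m[1:10, , ] <- 1L   # 1000 voxels left lung
  v1 <- image_volume(m, c(1, 1, 1))
  expect_equal(lung_volume(v1, "left"), 1.0)
  v2 <- image_volume(m, c(2, 2, 2))
  expect_equal(lung_volume(v2, "left"), 8.0)
  expect_equal(lung_volume(v2, "right"), 0)
  expect_equal(lung_volume(v2, "total"), 8.0)
})

test_that("sections are placed at fractional cranio-caudal positions", {
  # lung spanning 100 z-slices; apex is the most cranial (largest z) slice
  m <- array(0L, dim = c(10, 10, 120))
  m[4:7, 4:7, 10:109] <- 1L
  mask <- image_volume(m, c(2, 2, 2))
  s <- define_sections(mask, fractions = c(0.15, 0.40, 0.65, 0.88),
                       slab_thickness = 3)
  # apex = 109, base = 10; apical centre at 109 - 0.15 * 99
  expect_equal(s$slices$apical, (109 - round(0.15 * 99)) + (-1:1))
  expect_equal(length(s$slices$middle), 3)
  expect_true(all(diff(vapply(s$slices, mean, 0)) < 0))  # cranial to caudal

  s1 <- define_sections(mask, slab_thickness = 1)
  expect_true(all(lengths(s1$slices) == 1))

  expect_error(define_sections(mask, fractions = c(0.4, 0.45, 0.5, 0.55),
                               slab_thickness = 31), "overlap")
})

test_that("functional ratios saturate, vanish and flag empty intersections", {
  p <- cached_phantom()
  seg <- segment_lungs(p$exhale)
  sections <- define_sections(seg)
  all_on <- image_volume(array(1L, dim = dim(seg$data)), seg$spacing, seg$origin)
  r1 <- functional_ratio(all_on, seg, sections)
  expect_true(all(r1$ratio_pct[r1$n_voxels > 0] == 100))
  none <- image_volume(array(0L, dim = dim(seg$data)), seg$spacing, seg$origin)
  r0 <- functional_ratio(none, seg, sections)
  expect_true(all(r0$ratio_pct[r0$n_voxels > 0] == 0))
  expect_true(all(is.na(r0$ratio_pct[r0$n_voxels == 0])))
})

test_that("gravity-gradient phantom shows ratios rising toward the diaphragm", {
  p <- cached_phantom()
  seg <- segment_lungs(p$exhale)
  jm <- jacobian_map(p$truth_dvf)
  hf <- functional_mask(percentile_map(jm, seg))
  sections <- define_sections(seg)
  r <- functional_ratio(hf, seg, sections)
  for (lg in c("left", "right")) {
    rr <- r$ratio_pct[r$lung == lg]
    expect_true(all(diff(rr) > 0), label = paste(lg, "monotone toward diaphragm"))
    expect_gt(rr[4], rr[1])
  }
})

test_that("section ratios are invariant to uniform voxel rescaling", {
  p <- cached_phantom()
  seg <- segment_lungs(p$exhale)
  jm <- jacobian_map(p$truth_dvf)
  hf <- functional_mask(percentile_map(jm, seg))
  sections <- define_sections(seg)
  r1 <- functional_ratio(hf, seg, sections)
  # same arrays on a grid with half the voxel size
  seg2 <- image_volume(seg$data, seg$spacing / 2, seg$origin)
  hf2 <- image_volume(hf$data, hf$spacing / 2, hf$origin)
  r2 <- functional_ratio(hf2, seg2, sections)
  expect_equal(r1$ratio_pct, r2$ratio_pct)
  expect_equal(r2$volume_ml, r1$volume_ml / 8)
})
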