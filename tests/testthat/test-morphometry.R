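test_that("body segmentation keeps the largest component and fills holes", {
  expect_error(segment_body(matrix(-1000, 20, 20)), "empty body")

  slice <- matrix(-1000, 60, 60)
  slice[disc_mask(15, 60)] <- 40
  m <- segment_body(slice)
  expect_equal(m, disc_mask(15, 60))

  # interior hole gets filled; a small detached blob is discarded
  holey <- slice
  xs <- seq_len(60) - 30.5
  hole <- outer(xs, xs, function(a, b) a^2 + b^2 <= 4^2)
  holey[hole] <- -1000
  holey[2, 2] <- 40
  m2 <- segment_body(holey)
  expect_true(all(m2[hole]))
  expect_false(m2[2, 2])
})

test_that("sub-pixel perimeters match analytic values within 2%", {
  p_disc <- measure_circumference(disc_mask(50), c(1, 1))
  expect_equal(p_disc, 2 * pi * 50 / 10, tolerance = 0.02)

  sq <- matrix(FALSE, 120, 120)
  sq[11:110, 11:110] <- TRUE
  p_sq <- measure_circumference(sq, c(1, 1))
  expect_equal(p_sq, 40, tolerance = 0.02)

  # anisotropic spacing doubles the x-direction contribution
  p_iso <- measure_circumference(sq, c(1, 1))
  p_aniso <- measure_circumference(sq, c(2, 1))
  expect_equal(p_aniso, 1.5 * p_iso, tolerance = 0.01)

  expect_error(measure_circumference(matrix(FALSE, 5, 5), c(1, 1)), "empty")
})

test_that("perimeter and area are invariant to translation and 90-degree rotation", {
  base <- matrix(FALSE, 80, 80)
  base[20:50, 15:60] <- TRUE
  base[25:45, 20:40] <- TRUE
  shifted <- matrix(FALSE, 80, 80)
  shifted[28:58, 22:67] <- base[20:50, 15:60]
  rotated <- t(base)[, rev(seq_len(80))]

  expect_equal(measure_circumference(base, c(1, 1)),
               measure_circumference(shifted, c(1, 1)), tolerance = 1e-12)
  expect_equal(measure_circumference(base, c(1, 1)),
               measure_circumference(rotated, c(1, 1)), tolerance = 1e-12)
  expect_equal(sum(base), sum(rotated))
})

test_that("bone area is the scaled pixel count inside the HU window", {
  slice <- matrix(50, 30, 30)
  slice[1:10, 1:10] <- 500
  expect_equal(measure_bone_area(slice, c(1, 1)), 1.0)
  expect_equal(measure_bone_area(matrix(50, 10, 10), c(1, 1)), 0)
  expect_error(measure_bone_area(slice, c(1, 1), c(2000, 120)), "invalid")

  # monotone non-increasing as the lower threshold rises
  set.seed(3)
  rnd <- matrix(runif(400, 0, 2000), 20, 20)
  areas <- vapply(c(0, 120, 500, 1000, 1900),
                  function(lo) measure_bone_area(rnd, c(1, 1), c(lo, 2000)), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("synthetic bone area agrees with the generating disc geometry", {
  cs <- noiseless_spine()
  r <- cs$bone_radius
  dx <- cs$spacing[1]
  ring <- 2 * pi * r * dx / 100  # one-pixel boundary ring, cm2
  expect_lt(abs(cs$bone_area - pi * r^2 / 100), ring)
})

test_that("trabecular ROI means follow the protocol window and invert the line", {
  vol <- image_volume(array(150, dim = c(40, 40, 3)), c(1, 1, 1))
  expect_warning(m <- roi_mean_hu(vol, c(20, 20, 2), 7), "80-100")
  expect_equal(m, 150)
  expect_silent(m2 <- roi_mean_hu(vol, c(20, 20, 2), 5.35))
  expect_equal(m2, 150)

  cs <- noiseless_spine()
  mhu <- suppressWarnings(roi_mean_hu(cs$hu_volume, cs$roi_center, cs$roi_radius))
  roi <- disc_roi(cs$roi_center, cs$roi_radius, cs$spacing, dim(cs$truth_bmd))
  ref <- mean(cs$truth_bmd[(roi[, 3] - 1) * prod(dim(cs$truth_bmd)[1:2]) +
                             (roi[, 2] - 1) * dim(cs$truth_bmd)[1] + roi[, 1]])
  expect_equal(mhu, (ref - cs$true_beta) / cs$true_alpha, tolerance = 1e-10)
})

test_that("measured patient factors line up with the case ground truth", {
  cs <- noisy_spine()
  pf <- suppressWarnings(measure_patient_factors(cs$hu_volume, "spine"))
  expect_s3_class(pf, "patient_factors")
  expect_equal(pf$circumference, cs$circumference, tolerance = 0.01)
  expect_equal(pf$bone_area, cs$bone_area, tolerance = 0.05)
})
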