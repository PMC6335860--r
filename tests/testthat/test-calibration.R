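test_that("rod ROI means are arithmetic means with counts attached", {
  vox <- array(-1000, dim = c(4, 4, 1))
  vox[1, 1:4, 1] <- c(10, 10, 12, 8)
  vox[2, 1:2, 1] <- c(200, 220)
  vol <- image_volume(vox, c(1, 1, 1))
  roi1 <- cbind(y = rep(1L, 4), x = 1:4, z = rep(1L, 4))
  roi2 <- cbind(y = c(2L, 2L), x = 1:2, z = c(1L, 1L))
  rods <- extract_rod_means(vol, list(roi1, roi2), c(100, 400))
  expect_equal(rods$mean_hu, c(10, 210))
  expect_equal(rods$roi_voxel_count, c(4L, 2L))

  expect_error(extract_rod_means(vol, list(roi1, roi1), c(100, 400)), "overlap")
  bad <- cbind(y = 9L, x = 1L, z = 1L)
  expect_error(extract_rod_means(vol, list(roi1, bad), c(100, 400)), "bounds")
  expect_error(extract_rod_means(vol, list(roi1, roi2[0, , drop = FALSE]),
                                 c(100, 400)), "empty")
})

test_that("the calibration line is recovered exactly from exact rods", {
  two <- phantom_rod_set(c(0, 100), c(10, 210), c(5, 5))
  cal <- fit_calibration(two)
  expect_equal(cal$alpha, 0.5)
  expect_equal(cal$beta, -5)
  expect_equal(cal$r_squared, 1)

  d <- c(0, 50, 100, 200, 400)
  five <- phantom_rod_set(d, 2 * d + 10, rep(9, 5))
  cal5 <- fit_calibration(five)
  expect_equal(cal5$alpha, 0.5, tolerance = 1e-12)
  expect_equal(cal5$beta, -5, tolerance = 1e-10)

  expect_error(phantom_rod_set(100, 50, 4), "at least 2")
  expect_error(fit_calibration(phantom_rod_set(c(0, 100), c(7, 7), c(1, 1))),
               "singular")
})

test_that("calibration fitting is order-invariant and affine-equivariant", {
  set.seed(42)
  for (i in 1:20) {
    d <- sort(runif(5, 0, 400))
    hu <- d / runif(1, 0.5, 1.2) + rnorm(5, 0, 3)
    a <- fit_calibration(phantom_rod_set(d, hu, rep(4, 5)))
    perm <- sample(5)
    b <- fit_calibration(phantom_rod_set(d[perm], hu[perm], rep(4, 5)))
    expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
    expect_equal(a$beta, b$beta, tolerance = 1e-12)
    shift <- runif(1, -50, 50)
    s <- fit_calibration(phantom_rod_set(d, hu + shift, rep(4, 5)))
    expect_equal(s$alpha, a$alpha, tolerance = 1e-10)
    expect_equal(s$beta, a$beta - a$alpha * shift, tolerance = 1e-8)
  }
})

test_that("voxelwise application is the affine map with mask semantics", {
  vol <- image_volume(array(0, dim = c(3, 3, 2)), c(1, 1, 1))
  out <- apply_calibration(vol, calibration_model(1, 0))
  expect_true(all(out$values == 0))

  v700 <- image_volume(array(700, dim = c(2, 2, 1)), c(1, 1, 1))
  out2 <- apply_calibration(v700, calibration_model(0.848, 0))
  expect_equal(out2$values[1], 593.6)

  mask <- array(c(TRUE, FALSE), dim = c(2, 2, 1))
  out3 <- apply_calibration(v700, calibration_model(1, 5), mask)
  expect_true(all(is.na(out3$values[!mask])))
  expect_true(all(out3$values[mask] == 705))

  bad_mask <- array(TRUE, dim = c(3, 3, 1))
  expect_error(apply_calibration(v700, calibration_model(1, 0), bad_mask), "shape")
  expect_warning(calibration_model(-0.1, 0), "implausible")
})

test_that("zero-noise synthetic volumes round-trip to the truth field", {
  cs <- noiseless_spine()
  cal <- fit_calibration(extract_rod_means(cs$hu_volume, cs$rod_rois,
                                           cs$rod_densities))
  ref <- apply_calibration(cs$hu_volume, cal, cs$bone_mask)
  expect_lt(max(abs(ref$values[cs$bone_mask] - cs$truth_bmd[cs$bone_mask])), 1e-6)
})

test_that("calibration models survive the flat-file round trip", {
  cal <- calibration_model(0.848, -7.4, 0.9987, 5L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$alpha, cal$alpha)
  expect_equal(back$beta, cal$beta)
  expect_equal(back$r_squared, cal$r_squared)
  expect_equal(back$n_rods, cal$n_rods)
})
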