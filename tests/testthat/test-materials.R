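test_that("power-law moduli reproduce the worked values", {
  expect_equal(modulus_spine(1), 5124)
  expect_equal(modulus_spine(0), 0)
  expect_equal(modulus_spine(0.5), 1577.09599349, tolerance = 1e-10)
  expect_error(modulus_spine(-0.1), "non-negative")

  expect_equal(modulus_femur(1), 6850)
  expect_equal(modulus_femur(1.64), 14315.5456132, tolerance = 1e-10)  # low branch
  expect_equal(modulus_femur(2), 22502.0755311, tolerance = 1e-10)     # high branch
  expect_error(modulus_femur(c(1, -2)), "non-negative")

  # branch jump at the printed threshold is bounded, not smoothed away
  lo <- modulus_femur(1.64)
  hi <- 4293 * 1.64^2.39
  expect_lt(abs(hi - lo) / lo, 0.03)
})

test_that("the linear volume-fraction rule hits its endpoints and midpoint", {
  expect_equal(modulus_bvf(2000, c(0, 2000), 10200), 10200)
  expect_equal(modulus_bvf(0, c(0, 2000), 10200), 0)
  expect_equal(modulus_bvf(1000, c(0, 2000), 8400), 4200)
  expect_equal(modulus_bvf(-500, c(0, 2000), 8400), 0)    # clamped below
  expect_equal(modulus_bvf(3000, c(0, 2000), 8400), 8400) # clamped above
  expect_error(modulus_bvf(100, c(200, 100), 8400), "bounds")
  expect_error(material_law("linear_bvf", e0 = -1, intensity_bounds = c(0, 1)), "e0")
})

test_that("the laws are monotone except the documented femoral branch jump", {
  rho <- seq(0, 3, length.out = 400)
  expect_true(all(diff(modulus_spine(rho)) >= 0))
  hu <- seq(-100, 2500, length.out = 400)
  expect_true(all(diff(modulus_bvf(hu, c(0, 2000), 10200)) >= 0))
  # femur: monotone within each branch; the printed coefficients step DOWN
  # by ~2.2% across 1.64 g/cm3, so global monotonicity cannot hold
  lo_branch <- seq(0, 1.64, length.out = 200)
  hi_branch <- seq(1.6401, 3, length.out = 200)
  expect_true(all(diff(modulus_femur(lo_branch)) >= 0))
  expect_true(all(diff(modulus_femur(hi_branch)) >= 0))
})

test_that("linear BVF dominates the spine power law at equal maximum modulus", {
  rho_max <- 1.2
  rho <- seq(0.001, rho_max, length.out = 200)
  e3 <- modulus_spine(rho)
  # intensity proportional to density, bounds at rho = 0 and rho = rho_max
  e5 <- modulus_bvf(rho, c(0, rho_max), modulus_spine(rho_max))
  expect_true(all(e5 >= e3 - 1e-9))
  interior <- rho > 0.05 & rho < rho_max - 0.05
  expect_true(all(e5[interior] > e3[interior]))
})

test_that("material mapping bridges units, clamps, and floors", {
  blk <- make_uniform_block(c(2, 2, 2), 1000, 1)
  law <- material_law("spine_power")
  e <- map_materials(blk, law)
  expect_true(all(e == 5124))

  two <- bmd_volume(array(c(500, 1000), dim = c(2, 1, 1)), spacing = c(1, 1, 1))
  expect_equal(as.numeric(map_materials(two, law)),
               c(1577.09599349, 5124), tolerance = 1e-10)

  neg <- bmd_volume(array(-5, dim = c(1, 1, 1)), spacing = c(1, 1, 1))
  expect_equal(as.numeric(map_materials(neg, law)), law$modulus_floor)

  nan_vol <- bmd_volume(array(1, dim = c(2, 1, 1)), spacing = c(1, 1, 1))
  nan_vol$values[1] <- NaN
  expect_error(map_materials(nan_vol, law), "NaN")

  bvf_law <- material_law("linear_bvf", e0 = 8400, intensity_bounds = c(0, 2000))
  expect_error(map_materials(blk, bvf_law), "intensity")
  e_bvf <- map_materials(blk, bvf_law, intensity = array(1000, dim = dim(blk$values)))
  expect_true(all(e_bvf == 4200))
})
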