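test_that("published models carry the literature coefficients", {
  sp <- published_model("spine")
  expect_equal(c(sp$coef_hu, sp$coef_circumference, sp$intercept),
               c(0.848, 0.148, -7.4))
  hp <- published_model("hip")
  expect_equal(c(hp$coef_hu, hp$intercept), c(0.784, 16.6))
  expect_null(hp$coef_circumference)
  expect_identical(sp$source, "literature")
  expect_error(published_model("femur_shaft"), "site")
})

test_that("applying a conversion is the documented affine map", {
  sp <- published_model("spine")
  expect_equal(apply_conversion(700, list(circumference = 89.559, site = "spine"), sp),
               599.454732)
  hp <- published_model("hip")
  expect_equal(apply_conversion(500, list(site = "hip"), hp), 408.6)

  vol <- image_volume(array(0, dim = c(4, 4, 2)), c(1, 1, 1))
  out <- apply_conversion(vol, list(site = "hip"), hp)
  expect_s3_class(out, "bmd_volume")
  expect_true(all(out$values == 16.6))

  expect_error(apply_conversion(700, list(site = "spine"), sp), "missing factor")
  expect_error(apply_conversion(700, list(site = "hip", circumference = 80), sp),
               "site mismatch")

  # affinity: conversion of a mixture equals the mixture of conversions
  f <- list(circumference = 80, site = "spine")
  lam <- 0.3; a <- 250; b <- 900
  expect_equal(apply_conversion(lam * a + (1 - lam) * b, f, sp),
               lam * apply_conversion(a, f, sp) +
                 (1 - lam) * apply_conversion(b, f, sp),
               tolerance = 1e-12)
})

test_that("univariate screening separates real from null factors", {
  n <- 10
  hu <- seq(100, 300, length.out = n)
  tb <- cohort_table(data.frame(
    subject_id = sprintf("S%02d", 1:n), site = "spine", mean_hu = hu,
    circumference = 80, bone_area = 15, reference_bmd = 2 * hu))
  w <- capture_warnings(sc <- univariate_screen(tb))
  expect_length(grep("constant", w), 2)  # circumference and bone_area
  hu_row <- sc[sc$factor == "mean_hu", ]
  expect_equal(hu_row$slope, 2, tolerance = 1e-8)
  expect_lt(hu_row$p_value, 1e-8)
  expect_equal(sc$p_value[sc$factor == "circumference"], 1)

  # a factor independent of BMD stays insignificant in >= 90% of repeats
  set.seed(9)
  null_flags <- vapply(1:100, function(i) {
    x <- runif(200); y <- rnorm(200, 100, 10)
    tbl <- cohort_table(data.frame(
      subject_id = sprintf("S%03d", 1:200), site = "spine", mean_hu = y,
      circumference = 50 + 40 * x, bone_area = 15, reference_bmd = y))
    suppressWarnings(univariate_screen(tbl)$significant[2])
  }, NA)
  expect_gte(mean(!null_flags), 0.9)
})

test_that("stepwise refits recover generating coefficients and drop dead factors", {
  # noiseless: exact recovery of the published spine line
  tb0 <- published_recovery_cohort("spine", sigma = 0, seed = 3)
  fit0 <- suppressWarnings(fit_conversion(tb0, "spine"))  # perfect-fit warning
  expect_equal(fit0$coef_hu, 0.848, tolerance = 1e-8)
  expect_equal(fit0$coef_circumference, 0.148, tolerance = 1e-6)
  expect_equal(fit0$intercept, -7.4, tolerance = 1e-5)
  expect_null(fit0$coef_bone_area)  # filler column is eliminated

  # large-n near-noiseless cohort: coefficients within a tight band
  tbl <- published_recovery_cohort("spine", n = 200, sigma = 0.1, seed = 5)
  fitl <- fit_conversion(tbl, "spine")
  expect_equal(fitl$coef_hu, 0.848, tolerance = 0.005)
  expect_equal(fitl$coef_circumference, 0.148, tolerance = 0.05)

  # recovery error scales with the noise level
  errs <- vapply(c(0, 1, 2, 5), function(s) {
    f <- suppressWarnings(
      fit_conversion(published_recovery_cohort("spine", sigma = s, seed = 13),
                     "spine", candidates = c("mean_hu", "circumference")))
    abs(f$coef_hu - 0.848)
  }, 0)
  sd_hu <- sd(published_recovery_cohort("spine", sigma = 0, seed = 13)$mean_hu)
  expect_lt(errs[1], 1e-10)
  expect_true(all(errs <= pmax(1e-10, 6 * c(0, 1, 2, 5) / (sd_hu * sqrt(39)))))

  # hip: noiseless recovery, circumference eliminated
  th <- published_recovery_cohort("hip", sigma = 0, seed = 3)
  fh <- suppressWarnings(fit_conversion(th, "hip"))
  expect_equal(fh$coef_hu, 0.784, tolerance = 1e-8)
  expect_equal(fh$intercept, 16.6, tolerance = 1e-6)
  expect_null(fh$coef_circumference)
})

test_that("degenerate regressions are rejected", {
  tb <- published_recovery_cohort("spine", seed = 2)
  tb$bone_area <- 2 * tb$mean_hu  # exact collinearity
  expect_error(fit_conversion(tb, "spine"), "collinear")
  expect_error(fit_conversion(tb[1:3, ], "spine"), "insufficient")
  expect_error(fit_conversion(tb, "spine", candidates = "circumference"),
               "mean_hu")
  expect_error(univariate_screen(tb[1:3, ]), "at least 4")
})

test_that("the HU term dominates the circumference term over the printed ranges", {
  sp <- published_model("spine")
  hu <- seq(700, 1500, length.out = 33)
  circ <- seq(65.941, 97.356, length.out = 33)
  grid <- expand.grid(hu = hu, circ = circ)
  ratio <- (sp$coef_hu * grid$hu) / (sp$coef_circumference * grid$circ)
  expect_gte(min(ratio), 40)
})
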