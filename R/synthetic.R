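# Synthetic CT world with known ground truth. An axial body cross-section
# (soft-tissue ellipse around a bone disc with cortical shell and trabecular
# interior, a 5-rod calibration phantom below the body) is extruded along z.
# HU is generated from the truth BMD field through a patient-specific
# inverse calibration line whose intercept drifts with body circumference,
# so circumference carries information about the HU-to-BMD map -- the
# attenuation mechanism the phantomless conversion exists to absorb.

#' Generator settings for synthetic CT cases
#'
#' Defaults state the emulated world: the published circumference sampling
#' range (65.941-97.356 cm), 3 mm slices, a five-rod phantom at 0-400 mg/cc,
#' additive Gaussian HU noise of 5 HU, and site-specific inverse-calibration
#' coefficients equal to the published conversion lines (spine
#' alpha 0.848, intercept drifting as -7.4 + 0.148 * circumference; hip
#' alpha 0.784, fixed intercept 16.6). For the spine the mean trabecular
#' BMD also co-varies with circumference (3.5 mg/cc per cm, subject SD
#' 40 mg/cc), the body-size/density correlation that makes circumference
#' univariately significant at that site.
#'
#' @param site `"spine"` or `"hip"`.
#' @param ... overrides of the named defaults.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(site, ...) {
  site <- match_site(site)
  p <- list(
    site = site,
    n_xy = 160L, n_z = 8L,
    spacing = c(2.5, 2.5, 3),
    circumference_range = c(65.941, 97.356),
    body_aspect = 0.72,          # y semi-axis / x semi-axis
    soft_tissue_hu = c(35, 10),  # mean, sd; clipped to [0, 60]
    air_hu = -1000,
    cortical_thickness = 3,      # mm
    cortical_bmd = 900,          # mg/cc
    trabecular_bmd_mean = 180,
    trabecular_bmd_sd = 40,
    trabecular_bmd_range = c(120, 320),
    bmd_circ_slope = if (site == "spine") 3.5 else 0,  # mg/cc per cm
    spatial_bmd_amplitude = 30,
    noise_sd = 5,                # HU
    alpha = if (site == "spine") 0.848 else 0.784,     # mg/cc per HU
    beta0 = if (site == "spine") -7.4 else 16.6,       # mg/cc
    beta_slope = if (site == "spine") 0.148 else 0,    # mg/cc per cm
    rod_densities = c(0, 50, 100, 200, 400),
    rod_radius = 6,              # mm
    bone_radius_range = if (site == "spine") c(18, 27) else c(32, 45),
    roi_radius = 5.35            # mm -> ~90 mm2 trabecular ROI
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown generator parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (p$n_xy < 16L || p$n_z < 1L) stop("invalid parameter: non-positive or tiny grid")
  if (any(p$spacing <= 0)) stop("invalid parameter: spacing must be positive")
  if (p$noise_sd < 0) stop("invalid parameter: noise sd must be >= 0")
  if (any(diff(p$rod_densities) <= 0)) stop("rod densities must be strictly increasing")
  class(p) <- "generator_params"
  p
}

ellipse_semiaxis <- function(circ_mm, aspect) {
  h <- ((1 - aspect) / (1 + aspect))^2
  f <- 1 + 3 * h / (10 + sqrt(4 - 3 * h))
  circ_mm / (pi * (1 + aspect) * f)
}

#' Generate one synthetic CT case
#'
#' @param site `"spine"` or `"hip"`.
#' @param params a [generator_params()] list.
#' @param seed integer seed; generation is bit-reproducible.
#' @return An object of class `synthetic_case`: `hu_volume`
#'   ([image_volume]), `truth_bmd` (3-D array, mg/cc), `bone_mask`,
#'   `true_alpha`, `true_beta`, `circumference` (cm), `bone_area` (cm2),
#'   `rod_rois` + `rod_densities`, `roi_center`/`roi_radius` for the
#'   trabecular ROI, `site`, `seed`.
#' @export
generate_case <- function(site, params = generator_params(site), seed) {
  site <- match_site(site)
  stopifnot(inherits(params, "generator_params"))
  if (params$site != site) stop("params were built for site ", params$site)
  set.seed(as.integer(seed))

  target_circ <- stats::runif(1, params$circumference_range[1],
                              params$circumference_range[2])   # cm
  bone_radius <- stats::runif(1, params$bone_radius_range[1],
                              params$bone_radius_range[2])     # mm
  circ_mid <- mean(params$circumference_range)
  subj_bmd <- params$trabecular_bmd_mean +
    params$bmd_circ_slope * (target_circ - circ_mid) +
    stats::rnorm(1, 0, params$trabecular_bmd_sd)
  subj_bmd <- min(max(subj_bmd, params$trabecular_bmd_range[1]),
                  params$trabecular_bmd_range[2])

  n <- params$n_xy; nz <- params$n_z
  dx <- params$spacing[1]; dy <- params$spacing[2]
  width <- n * dx; height <- n * dy
  cx <- width / 2
  cy <- 0.45 * height
  xs <- (seq_len(n) - 0.5) * dx   # pixel-centre physical coords
  ys <- (seq_len(n) - 0.5) * dy
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)

  # rasterize the body ellipse, correcting the semi-axes against the
  # measured sub-pixel perimeter (2 fixed-point refinements)
  a <- ellipse_semiaxis(target_circ * 10, params$body_aspect)
  for (iter in 1:3) {
    b <- params$body_aspect * a
    body <- ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
    meas <- measure_circumference(body, params$spacing[1:2])
    if (iter < 3) a <- a * target_circ / meas
  }
  circumference <- meas
  if (a + 12 > width / 2 || b + 40 > height / 2)
    stop("body does not fit the grid; enlarge n_xy or reduce the circumference range")

  beta <- params$beta0 + params$beta_slope * circumference
  alpha <- params$alpha

  dist_bone <- sqrt((X - cx)^2 + (Y - cy)^2)
  trab_r <- bone_radius - params$cortical_thickness
  cortical <- body & dist_bone <= bone_radius & dist_bone > trab_r
  trabecular <- dist_bone <= trab_r

  # truth BMD on the slice: smooth radial modulation inside the trabecular
  # core, constant cortical shell
  bmd_slice <- matrix(NA_real_, n, n)
  # floor at 115 mg/cc keeps every bone voxel's HU above the 120 HU bone
  # window under both sites' calibration lines
  bmd_slice[trabecular] <- pmax(
    subj_bmd + params$spatial_bmd_amplitude *
      (1 - 2 * (dist_bone[trabecular] / trab_r)^2),
    115)
  bmd_slice[cortical] <- params$cortical_bmd

  # phantom rods below the body
  rod_r <- params$rod_radius
  rod_y <- cy + b + 12 + rod_r
  pitch <- 3 * 2 * rod_r
  n_rod <- length(params$rod_densities)
  rod_x <- cx + (seq_len(n_rod) - (n_rod + 1) / 2) * pitch
  rod_slice_mask <- vector("list", n_rod)
  for (i in seq_len(n_rod)) {
    rim <- (X - rod_x[i])^2 + (Y - rod_y)^2 <= rod_r^2
    bmd_slice[rim] <- params$rod_densities[i]
    rod_slice_mask[[i]] <- rim
  }

  bone2d <- cortical | trabecular
  solid2d <- bone2d | Reduce(`|`, rod_slice_mask)

  hu0_slice <- matrix(params$air_hu, n, n)
  hu0_slice[solid2d] <- (bmd_slice[solid2d] - beta) / alpha
  soft <- body & !solid2d
  n_soft <- sum(soft)
  hu0_slice[soft] <- pmin(pmax(
    stats::rnorm(n_soft, params$soft_tissue_hu[1], params$soft_tissue_hu[2]),
    0), 60)

  hu0 <- array(hu0_slice, dim = c(n, n, nz))
  truth_bmd <- alpha * hu0 + beta
  hu <- hu0
  if (params$noise_sd > 0)
    hu <- hu + array(stats::rnorm(length(hu0), 0, params$noise_sd), dim = dim(hu0))

  zc <- ceiling(nz / 2)
  rod_rois <- lapply(rod_slice_mask, function(m) {
    idx <- which(m, arr.ind = TRUE)
    cbind(y = idx[, 1], x = idx[, 2], z = rep(zc, nrow(idx)))
  })

  vol <- image_volume(hu, params$spacing)
  area_slice <- hu[, , zc]
  area_slice[!body] <- params$air_hu  # rods sit outside the body contour
  bone_area <- measure_bone_area(area_slice, params$spacing[1:2])
  roi_center <- c(x = cx / dx + 0.5, y = cy / dy + 0.5, z = zc)

  structure(list(
    hu_volume = vol,
    truth_bmd = truth_bmd,
    bone_mask = array(bone2d, dim = c(n, n, nz)),
    spacing = params$spacing,
    true_alpha = alpha, true_beta = beta,
    circumference = circumference,
    bone_area = bone_area,
    bone_radius = bone_radius,
    site = site,
    rod_rois = rod_rois,
    rod_densities = params$rod_densities,
    roi_center = roi_center, roi_radius = params$roi_radius,
    seed = as.integer(seed), params = params),
    class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case:%s> %s voxels, circumference %.2f cm, bone area %.2f cm2, alpha %.3f, beta %.2f\n",
              x$site, paste(dim(x$truth_bmd), collapse = "x"),
              x$circumference, x$bone_area, x$true_alpha, x$true_beta))
  invisible(x)
}

#' Generate a cohort of synthetic cases with its measurement table
#'
#' Per-subject factors are sampled independently; each table row is measured
#' from the case the way the clinical protocol prescribes: trabecular ROI
#' mean HU from the noisy volume, reference BMD as the ROI mean of the truth
#' field (the phantom-calibrated ground truth), circumference and bone area
#' from the central axial slice.
#'
#' With `table_only = TRUE` no volumes are rasterized: the same per-subject
#' factors are sampled and the table entries are computed from the
#' generator's closed-form ground truth (analytic ROI mean of the radial
#' BMD profile, HU noise attenuated by the ROI pixel count). This is the
#' fast path for repeat-heavy statistical checks; it emulates the same
#' stated world without the discretization of the voxel route.
#'
#' @param n cohort size (>= 3; the regression needs `p + 2` rows).
#' @param site `"spine"` or `"hip"`.
#' @param params a [generator_params()] list.
#' @param seed integer seed; per-case seeds are drawn from it.
#' @param table_only skip volume rasterization and build the table from the
#'   closed-form truth.
#' @return List with `cases` (list of [generate_case()] results, `NULL` when
#'   `table_only`) and `table` (a `cohort_table`).
#' @export
generate_cohort <- function(n, site, params = generator_params(site), seed,
                            table_only = FALSE) {
  if (n < 3L) stop("insufficient cohort: regression needs at least 3 subjects")
  set.seed(as.integer(seed))
  case_seeds <- sample.int(.Machine$integer.max, n)
  if (table_only) {
    circ_mid <- mean(params$circumference_range)
    roi_npix <- nrow(disc_roi(c(200, 200, 1), params$roi_radius,
                              params$spacing, c(400L, 400L, 1L)))
    rows <- lapply(seq_len(n), function(i) {
      set.seed(case_seeds[i])
      circ <- stats::runif(1, params$circumference_range[1],
                           params$circumference_range[2])
      bone_radius <- stats::runif(1, params$bone_radius_range[1],
                                  params$bone_radius_range[2])
      subj <- params$trabecular_bmd_mean +
        params$bmd_circ_slope * (circ - circ_mid) +
        stats::rnorm(1, 0, params$trabecular_bmd_sd)
      subj <- min(max(subj, params$trabecular_bmd_range[1]),
                  params$trabecular_bmd_range[2])
      trab_r <- bone_radius - params$cortical_thickness
      ref <- max(subj + params$spatial_bmd_amplitude *
                   (1 - params$roi_radius^2 / trab_r^2), 115)
      beta <- params$beta0 + params$beta_slope * circ
      mhu <- (ref - beta) / params$alpha +
        stats::rnorm(1, 0, params$noise_sd / sqrt(roi_npix))
      data.frame(subject_id = sprintf("S%03d", i), site = site,
                 mean_hu = mhu, circumference = circ,
                 bone_area = pi * bone_radius^2 / 100,
                 reference_bmd = ref)
    })
    return(list(cases = NULL, table = cohort_table(do.call(rbind, rows))))
  }
  cases <- lapply(case_seeds, function(s) generate_case(site, params, s))
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    roi <- disc_roi(cs$roi_center, cs$roi_radius, cs$spacing, dim(cs$truth_bmd))
    lin <- roi_to_linear(roi, dim(cs$truth_bmd))
    data.frame(
      subject_id = sprintf("S%03d", i),
      site = site,
      mean_hu = mean(cs$hu_volume$voxels[lin]),
      circumference = cs$circumference,
      bone_area = cs$bone_area,
      reference_bmd = mean(cs$truth_bmd[lin]))
  })
  list(cases = cases, table = cohort_table(do.call(rbind, rows)))
}

#' Uniform-density block for FEA verification
#'
#' @param shape `(nx, ny, nz)` voxel counts.
#' @param density constant density, mg/cc (>= 0).
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @return A [bmd_volume] whose mask covers every voxel.
#' @export
make_uniform_block <- function(shape, density, spacing = 1) {
  if (length(shape) != 3L || any(shape < 1L)) stop("all block dimensions must be >= 1")
  if (density < 0) stop("invalid parameter: density must be >= 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dims <- c(shape[2], shape[1], shape[3])  # (ny, nx, nz)
  bmd_volume(array(density, dim = dims), spacing = spacing)
}

#' Coefficient-recovery benchmark cohort
#'
#' The fixed simulation used to check that the stepwise refit recovers the
#' published conversion coefficients: 39 subjects, trabecular HU uniform on
#' (80, 300), circumference uniform on (66, 97) cm, reference BMD computed
#' from the published site model plus Gaussian noise (SD 2 mg/cc), seed 7.
#' Draw order is fixed (spine: HU, circumference, noise; hip: HU, noise,
#' circumference) so the realization is reproducible. Bone area is an
#' independent filler column (uniform on the site-typical range), present
#' only to satisfy the table schema.
#'
#' @param site `"spine"` or `"hip"`.
#' @param n cohort size.
#' @param sigma BMD noise SD, mg/cc.
#' @param seed integer seed.
#' @return A `cohort_table`.
#' @export
published_recovery_cohort <- function(site, n = 39, sigma = 2, seed = 7) {
  site <- match_site(site)
  set.seed(as.integer(seed))
  model <- published_model(site)
  if (site == "spine") {
    hu <- stats::runif(n, 80, 300)
    circ <- stats::runif(n, 66, 97)
    bmd <- model$coef_hu * hu + model$coef_circumference * circ +
      model$intercept + stats::rnorm(n, 0, sigma)
    area <- stats::runif(n, 10, 25)
  } else {
    hu <- stats::runif(n, 80, 300)
    bmd <- model$coef_hu * hu + model$intercept + stats::rnorm(n, 0, sigma)
    circ <- stats::runif(n, 66, 97)
    area <- stats::runif(n, 60, 90)
  }
  cohort_table(data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), site = site,
    mean_hu = hu, circumference = circ, bone_area = area,
    reference_bmd = bmd))
}
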