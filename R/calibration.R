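#' Phantom rod measurements
#'
#' Pairs each calibration rod's nominal mineral density with the mean HU
#' measured in its ROI. In-scan QCT phantoms carry rods of known
#' K2HPO4-equivalent density; the linear fit through these points anchors
#' the patient-specific HU-to-BMD map.
#'
#' @param nominal_density rod mineral densities, mg/cc.
#' @param mean_hu measured mean HU per rod.
#' @param roi_voxel_count voxels averaged per rod.
#' @return An object of class `phantom_rod_set`, ordered by density.
#' @export
phantom_rod_set <- function(nominal_density, mean_hu, roi_voxel_count) {
  n <- length(nominal_density)
  if (n < 2L) stop("at least 2 rods are required")
  if (length(mean_hu) != n || length(roi_voxel_count) != n)
    stop("rod fields must have equal length")
  if (any(roi_voxel_count < 1L)) stop("each rod ROI needs at least one voxel")
  ord <- order(nominal_density)
  nominal_density <- as.numeric(nominal_density[ord])
  if (any(diff(nominal_density) <= 0))
    stop("nominal densities must be strictly increasing")
  structure(list(nominal_density = nominal_density,
                 mean_hu = as.numeric(mean_hu[ord]),
                 roi_voxel_count = as.integer(roi_voxel_count[ord])),
            class = "phantom_rod_set")
}

#' Patient-specific calibration model
#'
#' The linear map `BMD = alpha * HU + beta` fitted from the in-scan phantom
#' rods of one examination.
#'
#' @param alpha slope, mg/cc per HU.
#' @param beta intercept, mg/cc.
#' @param r_squared coefficient of determination of the rod fit.
#' @param n_rods number of rods used.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(alpha, beta, r_squared = NA_real_, n_rods = NA_integer_) {
  if (!is.finite(alpha) || !is.finite(beta)) stop("alpha and beta must be finite")
  if (alpha <= 0)
    warning("fitted alpha <= 0: physically implausible HU-to-BMD slope")
  if (is.finite(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop("r_squared must lie in [0, 1]")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 r_squared = as.numeric(r_squared), n_rods = as.integer(n_rods)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> BMD = %.5g * HU + %.5g (r2 = %.5f, %d rods)\n",
              x$alpha, x$beta, x$r_squared, x$n_rods))
  invisible(x)
}

roi_to_linear <- function(roi, dims) {
  if (is.matrix(roi)) {
    if (ncol(roi) != 3L) stop("ROI index matrix must have 3 columns (y, x, z)")
    if (any(roi < 1L) || any(roi[, 1] > dims[1]) || any(roi[, 2] > dims[2]) ||
        any(roi[, 3] > dims[3]))
      stop("ROI indices fall outside the volume bounds")
    (roi[, 3] - 1L) * dims[1] * dims[2] + (roi[, 2] - 1L) * dims[1] + roi[, 1]
  } else {
    roi <- as.integer(roi)
    if (length(roi) && (min(roi) < 1L || max(roi) > prod(dims)))
      stop("ROI indices fall outside the volume bounds")
    roi
  }
}

#' Measure mean HU in each phantom rod ROI
#'
#' @param volume an [image_volume].
#' @param rod_rois list of ROI index sets, one per rod: either linear indices
#'   into the volume array or `n x 3` matrices of `(y, x, z)` voxel indices.
#'   ROIs must be disjoint and inside the volume.
#' @param nominal_densities rod densities, mg/cc, one per ROI.
#' @return A [phantom_rod_set] ordered by density.
#' @export
extract_rod_means <- function(volume, rod_rois, nominal_densities) {
  stopifnot(inherits(volume, "image_volume"))
  if (length(rod_rois) != length(nominal_densities))
    stop("one nominal density per ROI is required")
  dims <- dim(volume$voxels)
  lin <- lapply(rod_rois, roi_to_linear, dims = dims)
  if (any(lengths(lin) == 0L)) stop("empty rod ROI")
  all_idx <- unlist(lin)
  if (anyDuplicated(all_idx)) stop("rod ROIs overlap")
  phantom_rod_set(nominal_densities,
                  vapply(lin, function(i) mean(volume$voxels[i]), 0),
                  lengths(lin))
}

#' Fit the phantom calibration line
#'
#' Ordinary least squares of nominal density on mean HU, giving the
#' patient-specific `(alpha, beta)` and its r-squared.
#'
#' @param rods a [phantom_rod_set].
#' @return A [calibration_model].
#' @export
fit_calibration <- function(rods) {
  stopifnot(inherits(rods, "phantom_rod_set"))
  hu <- rods$mean_hu
  d <- rods$nominal_density
  if (diff(range(hu)) == 0)
    stop("singular calibration fit: all rod mean HU identical")
  fit <- stats::lm(d ~ hu)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  calibration_model(alpha = unname(stats::coef(fit)[2]),
                    beta = unname(stats::coef(fit)[1]),
                    r_squared = min(max(r2, 0), 1),
                    n_rods = length(hu))
}

#' Apply a calibration model voxelwise
#'
#' `BMD(v) = alpha * HU(v) + beta` for every masked voxel; voxels outside
#' the mask are flagged absent (`NA`).
#'
#' @param volume an [image_volume].
#' @param model a [calibration_model].
#' @param mask logical array of the volume's shape, or `NULL` for all voxels.
#' @return A [bmd_volume].
#' @export
apply_calibration <- function(volume, model, mask = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(model, "calibration_model"))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(volume$voxels))
  if (!identical(dim(mask), dim(volume$voxels)))
    stop("shape mismatch between mask and volume")
  bmd_volume(model$alpha * volume$voxels + model$beta, mask, volume$spacing)
}
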