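#' Image volume container
#'
#' A 3-D grid of Hounsfield units (HU) with physical voxel spacing. Arrays
#' are indexed `[y, x, z]` (1-based): rows run along the patient's
#' anterior-posterior axis, columns left-right, and the third index walks
#' axial slices. `spacing` is `(dx, dy, dz)` in millimetres.
#'
#' @param voxels 3-D numeric array of HU values. A 2-D matrix is promoted to
#'   a single-slice volume with a warning.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param intensity_offset HU offset already applied to the stored values
#'   (kept for provenance; 0 for calibrated scanners).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, intensity_offset = 0) {
  if (is.matrix(voxels)) {
    warning("2-D input promoted to a single-slice volume")
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (any(!is.finite(voxels)))
    stop("`voxels` contains non-finite values")
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         intensity_offset = as.numeric(intensity_offset)),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxelwise BMD volume
#'
#' Bone mineral density values (mg/cc) on the voxel grid, together with the
#' boolean mask of voxels for which the density is defined (bone voxels, or
#' every voxel for whole-slice comparisons). Values outside the mask are
#' stored as `NA`.
#'
#' @param values 3-D numeric array, mg/cc. `NA` allowed outside `mask`.
#' @param mask 3-D logical array, same shape as `values`.
#' @param spacing voxel spacing `(dx, dy, dz)` mm.
#' @return An object of class `bmd_volume`.
#' @export
bmd_volume <- function(values, mask = NULL, spacing) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  if (!identical(dim(values), dim(mask)))
    stop("shape mismatch between `values` and `mask`")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (any(!is.finite(values[mask])))
    stop("masked BMD values must be finite")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, spacing = as.numeric(spacing)),
            class = "bmd_volume")
}

#' @export
print.bmd_volume <- function(x, ...) {
  d <- dim(x$values)
  n <- sum(x$mask)
  cat(sprintf("<bmd_volume> %d x %d x %d voxels, %d in mask\n", d[1], d[2], d[3], n))
  if (n > 0)
    cat(sprintf("  BMD range [%.1f, %.1f] mg/cc\n",
                min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

match_site <- function(site) {
  if (length(site) != 1L || !site %in% c("spine", "hip"))
    stop("`site` must be \"spine\" or \"hip\"")
  site
}
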