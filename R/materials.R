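#' Density-to-modulus law for the vertebral body
#'
#' Power law `E = 5124 * rho^1.7` MPa with `rho` in g/cm3 (volumetric BMD
#' divided by 1000).
#'
#' @param rho density, g/cm3. Vectorized.
#' @return Young's modulus, MPa.
#' @export
modulus_spine <- function(rho) {
  if (any(rho < 0)) stop("density must be non-negative")
  5124 * rho^1.7
}

#' Density-to-modulus law for the proximal femur
#'
#' Piecewise power law: `E = 6850 * rho^1.49` MPa for `rho <= 1.64` g/cm3
#' and `E = 4293 * rho^2.39` MPa above. The threshold value itself takes the
#' low-density branch. The two branches meet within ~3% at the threshold;
#' the discontinuity is a property of the published coefficients and is not
#' smoothed away here.
#'
#' @param rho density, g/cm3. Vectorized.
#' @return Young's modulus, MPa.
#' @export
modulus_femur <- function(rho) {
  if (any(rho < 0)) stop("density must be non-negative")
  ifelse(rho <= 1.64, 6850 * rho^1.49, 4293 * rho^2.39)
}

#' Linear bone-volume-fraction modulus rule
#'
#' `E = E0 * BVF` where the volume fraction is the voxel intensity linearly
#' rescaled to \[0, 1\] between the pure-marrow and pure-bone intensities
#' (clamped outside the bounds). This is the simplified assignment widely
#' used when no calibrated BMD is available.
#'
#' @param intensity voxel intensity (HU). Vectorized.
#' @param bounds `(min, max)` intensities for pure marrow and pure bone.
#' @param e0 maximum modulus at BVF = 1, MPa.
#' @return Young's modulus, MPa.
#' @export
modulus_bvf <- function(intensity, bounds, e0) {
  if (bounds[1] >= bounds[2]) stop("invalid bounds: min must be < max")
  if (e0 <= 0) stop("e0 must be positive")
  bvf <- pmin(pmax((intensity - bounds[1]) / (bounds[2] - bounds[1]), 0), 1)
  e0 * bvf
}

#' Material law configuration
#'
#' @param kind `"spine_power"`, `"femur_piecewise"`, or `"linear_bvf"`.
#' @param e0 maximum modulus (MPa), required for `linear_bvf`.
#' @param intensity_bounds `(min, max)` HU for `linear_bvf`.
#' @param modulus_floor minimum element modulus, MPa; keeps the global
#'   stiffness matrix nonsingular for marrow-adjacent elements.
#' @param poisson Poisson's ratio (0.3 for both sites).
#' @return An object of class `material_law`.
#' @export
material_law <- function(kind = c("spine_power", "femur_piecewise", "linear_bvf"),
                         e0 = NULL, intensity_bounds = NULL,
                         modulus_floor = 0.01, poisson = 0.3) {
  kind <- match.arg(kind)
  if (modulus_floor <= 0) stop("modulus_floor must be positive")
  if (kind == "linear_bvf") {
    if (is.null(e0) || e0 <= 0) stop("linear_bvf requires a positive e0")
    if (is.null(intensity_bounds) || intensity_bounds[1] >= intensity_bounds[2])
      stop("linear_bvf requires intensity_bounds with min < max")
  }
  structure(list(kind = kind, e0 = e0, intensity_bounds = intensity_bounds,
                 modulus_floor = modulus_floor, poisson = poisson),
            class = "material_law")
}

#' Convert a BMD volume to per-element elastic moduli
#'
#' Density is bridged mg/cc -> g/cm3 (divide by 1000), negative estimates
#' (possible from phantomless conversion at low HU) are clamped to zero
#' before the power law, and the result is floored at `law$modulus_floor`.
#' Element order matches [build_mesh()]: linear index order of the masked
#' voxels.
#'
#' @param bmd a [bmd_volume] (for the power laws) whose mask defines the
#'   element set.
#' @param law a [material_law].
#' @param intensity for `linear_bvf` only: HU array (or [image_volume]) of
#'   the BMD volume's shape supplying the voxel intensities.
#' @return Numeric vector of per-element moduli (MPa), class `element_field`.
#' @export
map_materials <- function(bmd, law, intensity = NULL) {
  stopifnot(inherits(bmd, "bmd_volume"), inherits(law, "material_law"))
  vals <- bmd$values[bmd$mask]
  if (any(is.na(vals)) || any(!is.finite(vals)))
    stop("BMD volume contains NaN/NA inside its mask")
  e <- switch(law$kind,
    spine_power = modulus_spine(pmax(vals, 0) / 1000),
    femur_piecewise = modulus_femur(pmax(vals, 0) / 1000),
    linear_bvf = {
      if (is.null(intensity))
        stop("linear_bvf mapping needs the `intensity` volume")
      if (inherits(intensity, "image_volume")) intensity <- intensity$voxels
      if (!identical(dim(intensity), dim(bmd$values)))
        stop("intensity volume shape mismatch")
      modulus_bvf(intensity[bmd$mask], law$intensity_bounds, law$e0)
    })
  structure(pmax(e, law$modulus_floor), class = "element_field")
}
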