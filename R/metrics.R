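#' Voxelwise root-mean-square error between BMD fields
#'
#' `sqrt(sum((ref - est)^2) / n)` over the compared voxels -- population
#' normalization (divide by n, not n - 1). By default the comparison runs
#' over the intersection mask (bone voxels); pass `mask = NULL` with plain
#' arrays for whole-array parity with 512 x 512 reformatted slices.
#'
#' @param reference reference BMD: numeric array or [bmd_volume].
#' @param estimated estimated BMD, same shape.
#' @param mask logical array restricting the comparison; defaults to the
#'   intersection of the volumes' masks when both inputs are `bmd_volume`s,
#'   otherwise to all voxels.
#' @return RMSE in mg/cc.
#' @export
bmd_rmse <- function(reference, estimated, mask = NULL) {
  if (inherits(reference, "bmd_volume")) {
    if (is.null(mask)) mask <- reference$mask
    if (inherits(estimated, "bmd_volume")) mask <- mask & estimated$mask
    reference <- reference$values
  }
  if (inherits(estimated, "bmd_volume")) estimated <- estimated$values
  if (length(reference) != length(estimated) ||
      !identical(dim(reference), dim(estimated)))
    stop("shape mismatch between reference and estimated")
  if (is.null(mask)) mask <- rep(TRUE, length(reference))
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  sqrt(sum((reference[mask] - estimated[mask])^2) / n)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation and the p-value from the t transform with `n - 2`
#' degrees of freedom.
#'
#' @param x,y per-subject values, `n >= 3`, non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Relative total-strain-energy error
#'
#' `|estimated - reference| / reference * 100`.
#'
#' @param reference_total reference total strain energy, mJ (> 0).
#' @param estimated_total estimated total strain energy, mJ.
#' @return Error in percent.
#' @export
strain_energy_error <- function(reference_total, estimated_total) {
  if (reference_total <= 0) stop("reference total strain energy must be positive")
  abs(estimated_total - reference_total) / reference_total * 100
}

#' Bundle comparison statistics into a report
#'
#' @param rmse voxelwise RMSE, mg/cc.
#' @param pearson_r,pearson_p Pearson correlation of per-subject BMD values.
#' @param strain_energy_error_pct relative total strain energy error, percent.
#' @param n number of compared items.
#' @return An object of class `comparison_report`.
#' @export
comparison_report <- function(rmse = NA_real_, pearson_r = NA_real_,
                              pearson_p = NA_real_,
                              strain_energy_error_pct = NA_real_,
                              n = NA_integer_) {
  if (is.finite(rmse) && rmse < 0) stop("rmse must be non-negative")
  if (is.finite(pearson_r) && abs(pearson_r) > 1 + 1e-12)
    stop("pearson_r must lie in [-1, 1]")
  structure(list(rmse = rmse, pearson_r = pearson_r, pearson_p = pearson_p,
                 strain_energy_error_pct = strain_energy_error_pct,
                 n = n), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  RMSE                %.4g mg/cc\n", x$rmse))
  cat(sprintf("  Pearson r           %.4g (p = %.3g, n = %d)\n",
              x$pearson_r, x$pearson_p, x$n))
  cat(sprintf("  strain energy error %.4g %%\n", x$strain_energy_error_pct))
  invisible(x)
}
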