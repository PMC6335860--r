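#' Read a volume from a NIfTI-1 file
#'
#' Minimal single-file NIfTI-1 reader (`.nii` or `.nii.gz`). Supports the
#' common scalar datatypes (uint8, int16, int32, float32, float64) and honours
#' `scl_slope`/`scl_inter`. The on-disk x-fastest ordering is permuted into
#' the package's `[y, x, z]` array convention. Byte order is detected from
#' `sizeof_hdr`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("truncated NIfTI header: ", path)
  endian <- "little"
  sz <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  int16 <- function(off, n = 1L)
    readBin(raw_hdr[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2,
            endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(raw_hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4,
            endian = endian)
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unrecognized NIfTI magic: ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported: ", path)
  dims <- int16(40, 8L)
  ndim <- dims[1]
  if (!ndim %in% c(2L, 3L)) stop("only 2-D or 3-D NIfTI volumes supported")
  nx <- dims[2]; ny <- dims[3]; nz <- if (ndim >= 3L) max(dims[4], 1L) else 1L
  datatype <- int16(70)
  pixdim <- flt32(76, 8L)
  vox_offset <- flt32(108)
  scl_slope <- flt32(112); scl_inter <- flt32(116)
  spacing <- pixdim[2:4]
  if (ndim == 2L) spacing[3] <- if (pixdim[4] > 0) pixdim[4] else 1
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("NIfTI header carries no usable voxel spacing: ", path)
  type <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1, signed = FALSE),
    "4"  = list(what = "integer", size = 2, signed = TRUE),
    "8"  = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "double",  size = 4, signed = TRUE),
    "64" = list(what = "double",  size = 8, signed = TRUE),
    stop("unsupported NIfTI datatype code: ", datatype))
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- as.double(nx) * ny * nz
  vals <- readBin(con, type$what, n = n_vox, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data section: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vol <- array(as.numeric(vals), dim = c(nx, ny, nz))
  vol <- aperm(vol, c(2L, 1L, 3L))  # x-fastest on disk -> [y, x, z]
  if (ndim == 2L) warning("2-D input promoted to a single-slice volume")
  image_volume(vol, spacing)
}

#' Write a volume as NIfTI-1
#'
#' Writes float32 single-file NIfTI-1 (`.nii`, or gzip-compressed when the
#' path ends in `.gz`), with the voxel spacing in `pixdim` and a diagonal
#' sform. Lossless up to float32 precision.
#'
#' @param volume an [image_volume] or [bmd_volume] (masked-out voxels are
#'   written as 0).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "bmd_volume")) {
    vox <- volume$values
    vox[!volume$mask] <- 0
    volume <- image_volume(vox, volume$spacing)
  }
  if (!inherits(volume, "image_volume")) stop("`volume` must be an image_volume")
  d <- dim(volume$voxels)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  sp <- volume$spacing
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                       # sizeof_hdr
  wraw(10); wraw(18)                # data_type, db_name
  wi(0L, 4); wi(0L, 2)              # extents, session_error
  writeBin(charToRaw("r"), con)     # regular
  wraw(1)                           # dim_info
  wi(c(3L, nx, ny, nz, 1L, 1L, 1L, 1L), 2)   # dim
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2) # datatype float32, bitpix, slice_start
  wf(c(1, sp[1], sp[2], sp[3], 0, 0, 0, 0))  # pixdim
  wf(352); wf(1); wf(volume$intensity_offset)  # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wraw(1)                # slice_end, slice_code
  writeBin(as.raw(10L), con)        # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wraw(80); wraw(24)                # descrip, aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))           # quatern, qoffset
  wf(c(sp[1], 0, 0, 0)); wf(c(0, sp[2], 0, 0)); wf(c(0, 0, sp[3], 0))  # srow
  wraw(16)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                           # extension flag
  vox <- aperm(volume$voxels, c(2L, 1L, 3L))  # [y,x,z] -> x-fastest
  writeBin(as.numeric(vox), con, size = 4, endian = "little")
  invisible(path)
}

cohort_columns <- c("subject_id", "site", "mean_hu", "circumference",
                    "bone_area", "reference_bmd")

#' Validate and construct a cohort table
#'
#' One row per subject-site with the regression variables: trabecular ROI
#' mean HU, body circumference (cm), bone cross-sectional area (cm2), and
#' the phantom-calibrated reference BMD (mg/cc).
#'
#' @param df data frame carrying at least the canonical columns.
#' @return The validated data frame with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[cohort_columns]
  num <- c("mean_hu", "circumference", "bone_area", "reference_bmd")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (anyNA(df)) stop("cohort table contains missing values")
  if (any(df$reference_bmd <= 0)) stop("reference_bmd must be positive")
  if (any(df$circumference <= 0)) stop("circumference must be positive")
  if (any(df$bone_area < 0)) stop("bone_area must be non-negative")
  if (anyDuplicated(df[c("subject_id", "site")]))
    stop("duplicate subject_id/site rows in cohort table")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write a cohort table CSV
#'
#' @param path CSV path; the header is validated against the canonical
#'   cohort schema.
#' @return [read_cohort()]: a `cohort_table`; [write_cohort()]: `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df)
}

#' @rdname read_cohort
#' @param table a `cohort_table` (or coercible data frame).
#' @export
write_cohort <- function(table, path) {
  table <- cohort_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a comparison report as JSON
#'
#' @param report a `comparison_report` (see [comparison_report()]).
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "comparison_report")) stop("`report` must be a comparison_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "comparison_report")
}

#' Serialize a phantom calibration model
#'
#' Flat `key = value` text format holding `alpha`, `beta`, `r_squared` and
#' `n_rods`.
#'
#' @param model a `calibration_model`.
#' @param path output path.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  lines <- sprintf("%s = %.17g", c("alpha", "beta", "r_squared", "n_rods"),
                   c(model$alpha, model$beta, model$r_squared, model$n_rods))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, `[`, "", 1))
  need <- c("alpha", "beta", "r_squared", "n_rods")
  if (!all(need %in% names(vals)))
    stop("calibration file is missing field(s): ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  calibration_model(vals[["alpha"]], vals[["beta"]], vals[["r_squared"]],
                    as.integer(vals[["n_rods"]]))
}

#' Serialize a phantomless conversion model as YAML
#'
#' @param model a `conversion_model`.
#' @param path output `.yaml` path.
#' @export
write_conversion <- function(model, path) {
  stopifnot(inherits(model, "conversion_model"))
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_conversion
#' @export
read_conversion <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- yaml::read_yaml(path)
  conversion_model(site = obj$site, coef_hu = obj$coef_hu,
                   coef_circumference = obj$coef_circumference,
                   coef_bone_area = obj$coef_bone_area,
                   intercept = obj$intercept,
                   p_values = unlist(obj$p_values),
                   r_squared = obj$r_squared %||% NA_real_,
                   n_subjects = obj$n_subjects %||% NA_integer_,
                   source = obj$source %||% "fitted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
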