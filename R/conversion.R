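#' Phantomless HU-to-BMD conversion model
#'
#' Site-specific affine map from the trabecular HU value (and, where it
#' survives selection, patient physical factors) to volumetric BMD in mg/cc:
#' `BMD = coef_hu * HU + coef_circumference * C + coef_bone_area * A +
#' intercept`, with absent factors dropped.
#'
#' @param site `"spine"` or `"hip"`.
#' @param coef_hu mg/cc per HU (always present).
#' @param coef_circumference mg/cc per cm, or `NULL` if excluded.
#' @param coef_bone_area mg/cc per cm2, or `NULL` if excluded.
#' @param intercept mg/cc.
#' @param p_values named per-coefficient p-values (absent for
#'   literature-sourced models).
#' @param r_squared fit r-squared.
#' @param n_subjects fitted cohort size.
#' @param source `"fitted"` or `"literature"`.
#' @return An object of class `conversion_model`.
#' @export
conversion_model <- function(site, coef_hu, coef_circumference = NULL,
                             coef_bone_area = NULL, intercept,
                             p_values = NULL, r_squared = NA_real_,
                             n_subjects = NA_integer_, source = "fitted") {
  site <- match_site(site)
  if (!is.finite(coef_hu)) stop("coef_hu must be present and finite")
  if (!is.null(p_values) &&
      any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  structure(list(site = site, coef_hu = as.numeric(coef_hu),
                 coef_circumference = coef_circumference,
                 coef_bone_area = coef_bone_area,
                 intercept = as.numeric(intercept),
                 p_values = p_values, r_squared = r_squared,
                 n_subjects = n_subjects, source = source),
            class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  terms <- sprintf("%.4g * HU", x$coef_hu)
  if (!is.null(x$coef_circumference))
    terms <- c(terms, sprintf("%.4g * circumference", x$coef_circumference))
  if (!is.null(x$coef_bone_area))
    terms <- c(terms, sprintf("%.4g * bone_area", x$coef_bone_area))
  cat(sprintf("<conversion_model:%s> BMD = %s %+.4g  [%s]\n", x$site,
              paste(terms, collapse = " + "), x$intercept, x$source))
  invisible(x)
}

#' Published phantomless conversion models
#'
#' The literature coefficients for the two sites: spine
#' `BMD = 0.848 * HU + 0.148 * circumference - 7.4` and hip
#' `BMD = 0.784 * HU + 16.6` (BMD in mg/cc, circumference in cm). Marked
#' literature-sourced; no p-values are attached.
#'
#' @param site `"spine"` or `"hip"`.
#' @return A [conversion_model].
#' @export
published_model <- function(site) {
  site <- match_site(site)
  if (site == "spine")
    conversion_model("spine", coef_hu = 0.848, coef_circumference = 0.148,
                     intercept = -7.4, source = "literature")
  else
    conversion_model("hip", coef_hu = 0.784, intercept = 16.6,
                     source = "literature")
}

conversion_factors <- c("mean_hu", "circumference", "bone_area")

#' Univariate significance screen of the candidate factors
#'
#' Regresses the reference BMD on each candidate factor separately and
#' reports the slope and the two-sided t-test p-value; factors with
#' `p < alpha_level` are flagged significant. A constant factor column
#' raises a warning and reports `p = 1`.
#'
#' @param table a `cohort_table`.
#' @param alpha_level significance level, default 0.05.
#' @param candidates factor columns to screen.
#' @return Data frame with `factor`, `slope`, `p_value`, `significant`.
#' @export
univariate_screen <- function(table, alpha_level = 0.05,
                              candidates = conversion_factors) {
  table <- cohort_table(as.data.frame(table))
  if (nrow(table) < 4L) stop("univariate screen needs at least 4 rows")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must lie in (0, 1)")
  res <- lapply(candidates, function(fac) {
    x <- table[[fac]]
    if (diff(range(x)) == 0) {
      warning(sprintf("factor '%s' is constant: singular fit, p = 1 reported", fac))
      return(data.frame(factor = fac, slope = NA_real_, p_value = 1))
    }
    fit <- summary(stats::lm(table$reference_bmd ~ x))
    data.frame(factor = fac, slope = fit$coefficients[2, 1],
               p_value = fit$coefficients[2, 4])
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha_level
  out
}

#' Fit the phantomless conversion by stepwise regression
#'
#' Backward stepwise multiple OLS: all candidate factors enter a joint fit
#' of `reference_bmd` on the factors, then the least significant factor with
#' `p >= alpha_level` is dropped and the model refit, until every remaining
#' factor is significant. The HU term is never dropped (the conversion must
#' at minimum map HU to BMD). Setting `screen = TRUE` additionally gates
#' entry on the univariate p-value, the stricter variant; the default keeps
#' the joint-fit route, under which a factor whose effect is masked
#' marginally but certain conditionally (the usual situation for a
#' circumference term next to a dominant HU term) is still recoverable.
#'
#' @param table a `cohort_table`.
#' @param site `"spine"` or `"hip"`.
#' @param alpha_level retention threshold, default 0.05.
#' @param candidates candidate factor columns.
#' @param screen if `TRUE`, drop factors failing [univariate_screen()]
#'   before the joint fit.
#' @return A [conversion_model] with per-coefficient p-values and r-squared.
#' @export
fit_conversion <- function(table, site, alpha_level = 0.05,
                           candidates = conversion_factors, screen = FALSE) {
  table <- cohort_table(as.data.frame(table))
  site <- match_site(site)
  if (!"mean_hu" %in% candidates) stop("'mean_hu' must be among the candidates")
  factors <- candidates
  if (screen) {
    sc <- univariate_screen(table, alpha_level, candidates)
    factors <- union("mean_hu", sc$factor[sc$significant])
    factors <- intersect(candidates, factors)
  }
  if (nrow(table) < length(factors) + 2L)
    stop(sprintf("insufficient cohort: %d rows for %d factors (need >= p + 2)",
                 nrow(table), length(factors)))
  repeat {
    X <- as.matrix(table[factors])
    if (ncol(X) > 1L && kappa(cbind(1, scale(X, scale = FALSE))) > 1e8)
      stop("collinear surviving factors (condition number > 1e8)")
    fit <- stats::lm(stats::reformulate(factors, response = "reference_bmd"),
                     data = table)
    sm <- summary(fit)
    pv <- sm$coefficients[factors, 4]
    droppable <- setdiff(factors[pv >= alpha_level], "mean_hu")
    if (!length(droppable)) break
    worst <- droppable[which.max(pv[match(droppable, factors)])]
    factors <- setdiff(factors, worst)
  }
  cf <- stats::coef(fit)
  conversion_model(
    site = site,
    coef_hu = cf[["mean_hu"]],
    coef_circumference = if ("circumference" %in% factors) cf[["circumference"]],
    coef_bone_area = if ("bone_area" %in% factors) cf[["bone_area"]],
    intercept = cf[["(Intercept)"]],
    p_values = sm$coefficients[, 4],
    r_squared = sm$r.squared,
    n_subjects = nrow(table))
}

#' Apply a phantomless conversion model
#'
#' `BMD = coef_hu * HU + coef_circumference * C + coef_bone_area * A +
#' intercept`, elementwise for arrays and volumes. Predictions are a pure
#' affine map: negative outputs at very low HU are passed through unclamped
#' (clamping to zero happens at the material-mapping stage).
#'
#' @param hu scalar, array, or [image_volume] of HU values.
#' @param factors a `patient_factors` list (see
#'   [measure_patient_factors()]), or a list with the fields the model
#'   needs (`circumference`, `bone_area`, `site`).
#' @param model a [conversion_model].
#' @return BMD in mg/cc with the shape of `hu` (a [bmd_volume] for
#'   `image_volume` input).
#' @export
apply_conversion <- function(hu, factors, model) {
  stopifnot(inherits(model, "conversion_model"))
  if (!is.null(factors$site) && !identical(factors$site, model$site))
    stop(sprintf("site mismatch: factors are '%s' but model is '%s'",
                 factors$site, model$site))
  offset <- model$intercept
  if (!is.null(model$coef_circumference)) {
    if (is.null(factors$circumference))
      stop("missing factor: model requires `circumference`")
    offset <- offset + model$coef_circumference * factors$circumference
  }
  if (!is.null(model$coef_bone_area)) {
    if (is.null(factors$bone_area))
      stop("missing factor: model requires `bone_area`")
    offset <- offset + model$coef_bone_area * factors$bone_area
  }
  if (inherits(hu, "image_volume")) {
    bmd_volume(model$coef_hu * hu$voxels + offset, spacing = hu$spacing)
  } else {
    model$coef_hu * hu + offset
  }
}
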