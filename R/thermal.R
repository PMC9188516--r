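#' Fit a linear brain-temperature model to region means
#'
#' Ordinary least squares of the per-subject region means on brain
#' temperature, `y = a + b * x`, the model underlying the study's
#' temperature analysis. Confidence intervals of both coefficients are
#' t-based with n - 2 degrees of freedom; the p value is the two-sided t
#' test of the slope, which for simple regression equals the test of the
#' Pearson correlation.
#'
#' @param values Per-subject region means (one per subject).
#' @param temperatures Brain temperatures (degrees C), same length.
#' @param includes_invivo Flag recorded on the model: whether in vivo
#'   subjects are part of the data.
#' @param region,parameter Metadata recorded on the model.
#' @param conf_level Confidence level of the intervals.
#' @return An object of class `linear_temp_model`: `intercept_a`,
#'   `slope_b`, `ci_a`, `ci_b` (half-widths), `se_a`, `se_b`, `r2_adj`,
#'   `p_value`, `n_subjects`, `sigma` (residual SD), `includes_invivo`,
#'   `region`, `parameter_kind`.
#' @examples
#' x <- c(5, 10, 15, 20, 25, 36.5)
#' fit_linear_model(100 - 0.5 * x, x)
#' @export
fit_linear_model <- function(values, temperatures, includes_invivo = FALSE,
                             region = NA_character_,
                             parameter = NA_character_,
                             conf_level = 0.95) {
  if (length(values) != length(temperatures))
    stop("values and temperatures must have equal length")
  ok <- is.finite(values) & is.finite(temperatures)
  values <- values[ok]; temperatures <- temperatures[ok]
  n <- length(values)
  if (n < 3) stop("at least 3 subjects are required")
  if (stats::var(temperatures) == 0)
    stop("degenerate design: all temperatures identical")
  fit <- stats::lm(values ~ temperatures)
  # synthetic noiseless inputs legitimately produce perfect fits; the
  # corresponding summary.lm warning is not informative here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(list(
    intercept_a = unname(co[1, 1]), slope_b = unname(co[2, 1]),
    se_a = unname(co[1, 2]), se_b = unname(co[2, 2]),
    ci_a = unname(tcrit * co[1, 2]), ci_b = unname(tcrit * co[2, 2]),
    r2_adj = sm$adj.r.squared,
    p_value = unname(co[2, 4]),
    n_subjects = n, sigma = sm$sigma,
    includes_invivo = includes_invivo,
    region = region, parameter_kind = parameter,
    conf_level = conf_level), class = "linear_temp_model")
}

#' @export
print.linear_temp_model <- function(x, ...) {
  cat(sprintf("Linear temperature model%s%s (%s in vivo, n = %d)\n",
              if (is.na(x$region)) "" else paste0(": ", x$region),
              if (is.na(x$parameter_kind)) "" else paste0(" ", x$parameter_kind),
              if (x$includes_invivo) "with" else "without", x$n_subjects))
  cat(sprintf("  a = %.6g +/- %.3g, b = %.6g +/- %.3g (95%% CI half-widths)\n",
              x$intercept_a, x$ci_a, x$slope_b, x$ci_b))
  cat(sprintf("  adj. R2 = %.3f, p = %.4g\n", x$r2_adj, x$p_value))
  invisible(x)
}

#' Build a linear_temp_model directly from tabulated coefficients
#'
#' Wraps a row of [temperature_coefficients()] (or any `(a, b)` pair) in
#' the model class so that prediction and correction helpers can consume
#' published coefficients.
#'
#' @param a,b Intercept and slope.
#' @param ci_a,ci_b Optional 95% half-widths.
#' @param region,parameter,includes_invivo Metadata.
#' @return A `linear_temp_model`.
#' @export
as_linear_temp_model <- function(a, b, ci_a = NA_real_, ci_b = NA_real_,
                                 region = NA_character_,
                                 parameter = NA_character_,
                                 includes_invivo = FALSE) {
  structure(list(intercept_a = a, slope_b = b, se_a = NA_real_,
                 se_b = NA_real_, ci_a = ci_a, ci_b = ci_b,
                 r2_adj = NA_real_, p_value = NA_real_,
                 n_subjects = NA_integer_, sigma = NA_real_,
                 includes_invivo = includes_invivo, region = region,
                 parameter_kind = parameter, conf_level = 0.95),
            class = "linear_temp_model")
}

#' Model value at a given brain temperature
#'
#' @param model A `linear_temp_model`.
#' @param temperature Degrees C (vectorised).
#' @return `a + b * temperature`.
#' @export
predict_at <- function(model, temperature) {
  model$intercept_a + model$slope_b * temperature
}

#' Percentage difference between post-mortem extrapolation and in vivo mean
#'
#' Delta* statistic: how far the post-mortem-only model, extrapolated to
#' the living brain temperature of 36.5 degrees C, falls from the measured
#' mean in vivo value (taken as 100%). Positive when the extrapolation
#' exceeds the in vivo mean. A non-zero Delta* indicates non-temperature
#' post mortem effects (for MD, chiefly the loss of perfusion and active
#' diffusion).
#'
#' @param model_without_invivo Post-mortem-only `linear_temp_model`.
#' @param measured_invivo_mean Measured mean in vivo value (non-zero).
#' @param invivo_temperature Living brain temperature (degrees C).
#' @return Percentage difference.
#' @export
delta_star <- function(model_without_invivo, measured_invivo_mean,
                       invivo_temperature = 36.5) {
  if (!is.finite(measured_invivo_mean) || measured_invivo_mean == 0)
    stop("measured in vivo mean must be finite and non-zero")
  pred <- predict_at(model_without_invivo, invivo_temperature)
  100 * (pred - measured_invivo_mean) / measured_invivo_mean
}

#' Percentage difference across the post mortem temperature span
#'
#' Delta** statistic: percentage difference between the model values at
#' 4 degrees C (cooled body) and 36.5 degrees C (living brain), with the
#' 36.5 degree value taken as 100%, computed on the post-mortem-only fit.
#' It quantifies the pure temperature contribution to a post mortem
#' parameter and is invariant to rescaling the parameter's units.
#'
#' @param model_without_invivo Post-mortem-only `linear_temp_model`.
#' @param cold_temperature,invivo_temperature The two temperatures
#'   compared (degrees C).
#' @return Percentage difference.
#' @export
delta_double_star <- function(model_without_invivo, cold_temperature = 4,
                              invivo_temperature = 36.5) {
  ref <- predict_at(model_without_invivo, invivo_temperature)
  if (!is.finite(ref) || ref == 0)
    stop("model value at the reference temperature must be non-zero")
  100 * (predict_at(model_without_invivo, cold_temperature) - ref) / ref
}

#' Temperature correction of a quantitative parameter value
#'
#' Transports a measured value along the fitted temperature line from the
#' temperature it was measured at to a reference temperature:
#' `value + b * (reference - measured)`. Exactly invertible and additive
#' in temperature. The post-mortem-only slope is the recommended choice
#' for correcting post mortem data, since the with-invivo line absorbs
#' non-temperature effects (large Delta*, especially for MD and FA).
#'
#' @param value Measured parameter value(s).
#' @param measured_temp Temperature at measurement (degrees C).
#' @param reference_temp Temperature to correct to (degrees C); values
#'   outside [0, 40] trigger a range warning.
#' @param model A `linear_temp_model` supplying the slope.
#' @return Corrected value(s).
#' @examples
#' m <- as_linear_temp_model(a = 105.4, b = -0.6)
#' correct_to_temperature(100, measured_temp = 10, reference_temp = 36.5, m)
#' @export
correct_to_temperature <- function(value, measured_temp, reference_temp,
                                   model) {
  if (!is.finite(model$slope_b)) stop("model slope must be finite")
  if (any(reference_temp < 0 | reference_temp > 40))
    warning("reference temperature outside the supported 0-40 degree range")
  value + model$slope_b * (reference_temp - measured_temp)
}

#' Compare the with- and without-invivo fit variants
#'
#' A discrepancy between the two fitted lines at living brain temperature
#' indicates physiological processes beyond temperature (loss of
#' perfusion, ceased metabolism). The report gives both predictions at
#' 36.5 degrees C, their difference and percentage difference, whether the
#' slope confidence intervals overlap, and -- when the measured in vivo
#' mean is supplied -- the Delta* statistic.
#'
#' @param model_with,model_without The two `linear_temp_model` fits of the
#'   same region/parameter.
#' @param invivo_mean Optional measured mean in vivo value for Delta*.
#' @param invivo_temperature Living brain temperature (degrees C).
#' @return A list of class `fit_variant_comparison`.
#' @export
compare_fit_variants <- function(model_with, model_without,
                                 invivo_mean = NULL,
                                 invivo_temperature = 36.5) {
  pred_with <- predict_at(model_with, invivo_temperature)
  pred_without <- predict_at(model_without, invivo_temperature)
  slope_overlap <- NA
  if (is.finite(model_with$ci_b) && is.finite(model_without$ci_b)) {
    lo_w <- model_with$slope_b - model_with$ci_b
    hi_w <- model_with$slope_b + model_with$ci_b
    lo_o <- model_without$slope_b - model_without$ci_b
    hi_o <- model_without$slope_b + model_without$ci_b
    slope_overlap <- lo_w <= hi_o && lo_o <= hi_w
  }
  structure(list(
    region = model_without$region,
    parameter_kind = model_without$parameter_kind,
    prediction_with = pred_with,
    prediction_without = pred_without,
    difference = pred_without - pred_with,
    pct_difference = if (pred_with != 0)
      100 * (pred_without - pred_with) / pred_with else NA_real_,
    slope_ci_overlap = slope_overlap,
    delta_star = if (!is.null(invivo_mean))
      delta_star(model_without, invivo_mean, invivo_temperature)
    else NA_real_),
    class = "fit_variant_comparison")
}

#' @export
print.fit_variant_comparison <- function(x, ...) {
  cat("Fit-variant comparison",
      if (!is.na(x$region)) paste0("(", x$region, " ", x$parameter_kind, ")"),
      "\n")
  cat(sprintf("  prediction at 36.5 C: with = %.6g, without = %.6g (%+.1f%%)\n",
              x$prediction_with, x$prediction_without, x$pct_difference))
  cat("  slope CIs overlap:", x$slope_ci_overlap, "\n")
  if (is.finite(x$delta_star))
    cat(sprintf("  Delta* = %+.1f%%\n", x$delta_star))
  invisible(x)
}

#' Fit both temperature-model variants for every region/parameter cell
#'
#' Driver over a cohort summary table: for each region and parameter it
#' fits the linear temperature model once on all subjects
#' (`with_invivo`) and once on the post mortem subjects only
#' (`without_invivo`), and derives the Delta statistics when in vivo
#' subjects are present.
#'
#' @param summaries Data frame in the [generate_cohort()] /
#'   [summarize_subject()] schema.
#' @return A data frame with one row per region x parameter x variant and
#'   the fitted coefficients, plus attribute `models`, a nested list of
#'   the `linear_temp_model` objects and comparisons.
#' @export
fit_cohort_models <- function(summaries) {
  cells <- unique(summaries[, c("region", "parameter")])
  out <- list(); models <- list()
  for (i in seq_len(nrow(cells))) {
    region <- cells$region[i]; parameter <- cells$parameter[i]
    d <- summaries[summaries$region == region &
                   summaries$parameter == parameter, ]
    pm <- d[d$cohort == "post_mortem", ]
    iv <- d[d$cohort == "in_vivo", ]
    m_wo <- fit_linear_model(pm$mean, pm$temperature_C,
                             includes_invivo = FALSE,
                             region = region, parameter = parameter)
    m_w <- NULL; comp <- NULL
    invivo_mean <- if (nrow(iv) > 0) mean(iv$mean) else NULL
    if (nrow(iv) > 0) {
      m_w <- fit_linear_model(d$mean, d$temperature_C,
                              includes_invivo = TRUE,
                              region = region, parameter = parameter)
      comp <- compare_fit_variants(m_w, m_wo, invivo_mean = invivo_mean)
    }
    models[[paste(region, parameter)]] <-
      list(with_invivo = m_w, without_invivo = m_wo, comparison = comp)
    mk_row <- function(m, variant) data.frame(
      region = region, parameter = parameter, variant = variant,
      a = m$intercept_a, ci_a = m$ci_a, b = m$slope_b, ci_b = m$ci_b,
      r2_adj = m$r2_adj, p_value = m$p_value, n_subjects = m$n_subjects,
      delta_star = if (variant == "without_invivo" && !is.null(invivo_mean))
        delta_star(m, invivo_mean) else NA_real_,
      delta_double_star = if (variant == "without_invivo")
        delta_double_star(m) else NA_real_,
      stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- mk_row(m_wo, "without_invivo")
    if (!is.null(m_w)) out[[length(out) + 1]] <- mk_row(m_w, "with_invivo")
  }
  res <- do.call(rbind, out)
  attr(res, "models") <- models
  res
}
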