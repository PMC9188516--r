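#' Draw from a truncated normal distribution
#'
#' Simple rejection sampler; adequate for the mild truncation used for
#' post mortem brain temperatures.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("invalid truncation range")
  if (upper < mean - 5 * sd || lower > mean + 5 * sd)
    stop("truncation range excludes mean +/- 5 SD; infeasible configuration")
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Deterministic per-subject seed derived from the run seed; keeps cohort
# generation invariant to subject ordering and below 2^31.
derive_seed <- function(seed, index) {
  as.integer(((seed %% 65536) * 32749 + index * 7919 + 1) %% 2147483647)
}

#' Residual SD implied by a printed slope confidence interval
#'
#' The cohort generator needs per-region, per-parameter residual SDs, but
#' the source tables print none. This helper inverts the OLS slope CI
#' half-width, `ci_b = t * s / sqrt(Sxx)`, under the nominal study design
#' (`n` subjects whose temperatures have SD `temp_sd`), giving a residual
#' SD consistent with the printed uncertainty.
#'
#' @param ci_b 95% half-width of the slope.
#' @param n Number of subjects in the fit.
#' @param temp_sd SD of the subject temperatures (degrees C).
#' @return Residual SD in parameter units.
#' @export
residual_sd_from_ci <- function(ci_b, n = 16, temp_sd = 5.7) {
  sxx <- (n - 1) * temp_sd^2
  ci_b * sqrt(sxx) / stats::qt(0.975, df = n - 2)
}

#' Generate a synthetic cohort of region-mean summaries
#'
#' Emulates the study cohort: `n_post_mortem` deceased subjects whose
#' brain temperatures follow a truncated normal distribution (default
#' 12.7 +/- 5.7 degrees C on [5.6, 28.1]), plus `n_in_vivo` living
#' subjects at exactly 36.5 degrees C. Every subject's per-region,
#' per-parameter mean is the linear temperature model value plus a
#' Gaussian residual whose SD defaults to the value implied by the printed
#' slope confidence interval (see [residual_sd_from_ci()]).
#'
#' `invivo_scale` multiplies the in vivo model value, which injects a
#' controlled discrepancy between the two fit variants: a scale of 2 on MD
#' makes the post-mortem-only extrapolation at 36.5 degrees fall 50% below
#' the measured in vivo mean, emulating the loss of perfusion and active
#' diffusion after death.
#'
#' @param n_post_mortem,n_in_vivo Cohort sizes (post mortem >= 3).
#' @param temp_mean,temp_sd,temp_range Truncated-normal parameters of the
#'   post mortem brain temperatures (degrees C).
#' @param regions,parameters Which region/parameter cells to generate.
#' @param residual_sd_table Optional data frame `(region, parameter, sd)`
#'   overriding the CI-derived residual SDs.
#' @param coefficient_table See [temperature_coefficients()].
#' @param variant Which fitted line generates the data.
#' @param invivo_scale Named numeric vector (by parameter) scaling the in
#'   vivo model value; unnamed scalar applies to all parameters.
#' @param seed Integer run seed; all randomness derives from it.
#' @return A list with `subjects` (list of [subject_spec()]) and
#'   `summaries`, a data frame with columns `subject_id`, `cohort`,
#'   `temperature_C`, `region`, `parameter`, `mean`, `sd`, `n_voxels`.
#' @export
generate_cohort <- function(n_post_mortem = 16, n_in_vivo = 4,
                            temp_mean = 12.7, temp_sd = 5.7,
                            temp_range = c(5.6, 28.1),
                            regions = setdiff(unique(temperature_coefficients()$region),
                                              "deep_gray_matter"),
                            parameters = c("T1", "T2", "T2star", "MD", "FA"),
                            residual_sd_table = NULL,
                            coefficient_table = temperature_coefficients(),
                            variant = c("without_invivo", "with_invivo"),
                            invivo_scale = 1,
                            seed = 1L) {
  variant <- match.arg(variant)
  if (n_post_mortem < 3)
    stop("at least 3 post mortem subjects are required for fitting")
  if (temp_range[1] <= 0 || temp_range[2] >= 37)
    stop("post mortem temperature range must lie within (0, 37)")

  scale_for <- function(parameter) {
    if (is.null(names(invivo_scale))) invivo_scale[1]
    else if (parameter %in% names(invivo_scale)) invivo_scale[[parameter]]
    else 1
  }
  sd_for <- function(region, parameter) {
    if (!is.null(residual_sd_table)) {
      row <- residual_sd_table[residual_sd_table$region == region &
                               residual_sd_table$parameter == parameter, ]
      if (nrow(row) == 1) return(row$sd)
    }
    row <- coefficient_table[coefficient_table$region == region &
                             coefficient_table$parameter == parameter &
                             coefficient_table$variant == variant, ]
    if (nrow(row) != 1)
      stop("no coefficient row for (", region, ", ", parameter, ")")
    residual_sd_from_ci(row$ci_b, n = n_post_mortem, temp_sd = temp_sd)
  }

  n_total <- n_post_mortem + n_in_vivo
  subjects <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sseed <- derive_seed(seed, i)
    is_pm <- i <= n_post_mortem
    temp <- if (is_pm) {
      with_seed(sseed, rtruncnorm_reject(1, temp_mean, temp_sd,
                                         temp_range[1], temp_range[2]))
    } else 36.5
    sid <- sprintf("%s%02d", if (is_pm) "pm" else "iv",
                   if (is_pm) i else i - n_post_mortem)
    subjects[[i]] <- subject_spec(sid, if (is_pm) "post_mortem" else "in_vivo",
                                  temp, seed = sseed,
                                  pm_range = temp_range)
    cells <- expand.grid(region = regions, parameter = parameters,
                         stringsAsFactors = FALSE)
    means <- numeric(nrow(cells))
    sds <- numeric(nrow(cells))
    with_seed(derive_seed(sseed, 99991), {
      for (j in seq_len(nrow(cells))) {
        base <- ground_truth_value(cells$region[j], cells$parameter[j],
                                   temp, coefficient_table, variant)
        if (!is_pm) base <- base * scale_for(cells$parameter[j])
        s <- sd_for(cells$region[j], cells$parameter[j])
        means[j] <- base + stats::rnorm(1, 0, s)
        sds[j] <- s
      }
    })
    rows[[i]] <- data.frame(subject_id = sid,
                            cohort = subjects[[i]]$cohort,
                            temperature_C = temp,
                            region = cells$region,
                            parameter = cells$parameter,
                            mean = means, sd = sds, n_voxels = 1L,
                            stringsAsFactors = FALSE)
  }
  list(subjects = subjects, summaries = do.call(rbind, rows))
}

#' Write cohort summaries and their generation parameters
#'
#' Writes the summary data frame as CSV and, when `params` is given, a
#' JSON sidecar echoing every generation parameter.
#'
#' @param cohort Output of [generate_cohort()].
#' @param csv_path Output CSV path.
#' @param params Optional named list echoed to `<csv_path>.json`.
#' @return `csv_path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, csv_path, params = NULL) {
  utils::write.csv(cohort$summaries, csv_path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(csv_path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
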