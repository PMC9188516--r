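#' Published linear temperature-model coefficients
#'
#' Loads the packaged table of fitted linear brain-temperature models
#' `y = a + b * temperature` for the five quantitative parameters (T1, T2,
#' T2*, MD, FA) in seven brain regions (white matter, cerebral cortex,
#' deep gray matter, globus pallidus, putamen, caudate nucleus, thalamus),
#' each in two variants: fitted with (`with_invivo`) and without
#' (`without_invivo`) the in vivo reference subjects. Columns:
#'
#' * `a`, `b`: intercept (parameter units) and slope (units per degree C);
#' * `ci_a`, `ci_b`: 95% confidence half-widths of `a` and `b`;
#' * `r2_adj`: adjusted R squared; `p_value`: slope-test p value and
#'   `p_censored`: `TRUE` where the source prints "< 0.001";
#' * `delta_star`: percentage difference between the measured mean in vivo
#'   value and the 36.5 degree prediction of the post-mortem-only fit
#'   (printed on `with_invivo` rows);
#' * `delta_double_star`: percentage difference between the 4 and the
#'   36.5 degree model values of the post-mortem-only fit (printed on
#'   `without_invivo` rows);
#' * `a_printed`, `b_printed`: the coefficients exactly as printed, kept
#'   so that printed precision can be propagated;
#' * `a_half_ulp`, `b_half_ulp`: half of the last printed digit's value.
#'
#' T1, T2 and T2* are in ms, MD in mm2/s, FA dimensionless.
#'
#' @param path Optional path to an alternative CSV with the same layout.
#' @return A data frame with one row per region x parameter x variant.
#' @examples
#' tab <- temperature_coefficients()
#' subset(tab, region == "putamen" & parameter == "T1")
#' @export
temperature_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "temperature_coefficients.csv",
                        package = "pmqmri", mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = "character")
  out <- data.frame(
    region = raw$region,
    parameter = raw$parameter,
    variant = raw$variant,
    a = as.numeric(raw$a),
    ci_a = as.numeric(raw$ci_a),
    b = as.numeric(raw$b),
    ci_b = as.numeric(raw$ci_b),
    r2_adj = as.numeric(raw$r2_adj),
    p_value = ifelse(grepl("^<", raw$p), 0.001,
                     suppressWarnings(as.numeric(raw$p))),
    p_censored = grepl("^<", raw$p),
    delta_star = suppressWarnings(as.numeric(raw$delta_star)),
    delta_double_star = suppressWarnings(as.numeric(raw$delta_double_star)),
    a_printed = raw$a,
    b_printed = raw$b,
    stringsAsFactors = FALSE)
  out$a_half_ulp <- vapply(raw$a, printed_half_ulp, numeric(1))
  out$b_half_ulp <- vapply(raw$b, printed_half_ulp, numeric(1))
  out
}

# Half the value of the last printed decimal digit, e.g. "105.4" -> 0.05,
# "1.0E-04" -> 5e-6. Used to bound rounding of printed coefficients.
printed_half_ulp <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec(
    "^-?([0-9]+)(\\.([0-9]+))?([Ee](-?[0-9]+))?$", s))[[1]]
  if (length(m) == 0) stop("cannot parse printed number: ", s)
  decimals <- nchar(m[4])
  expo <- if (m[6] == "") 0 else as.numeric(m[6])
  0.5 * 10^(expo - decimals)
}

#' Evaluate a linear temperature model from the coefficient table
#'
#' Looks up the `(region, parameter, variant)` row and returns the model
#' value `a + b * temperature`, the region's expected parameter value at a
#' given brain temperature. This is the ground truth the synthetic phantom
#' and cohort generators are built on.
#'
#' @param region,parameter,variant Row key; see [temperature_coefficients()].
#' @param temperature Brain temperature in degrees C (vectorised).
#' @param coefficient_table Table as returned by
#'   [temperature_coefficients()].
#' @return Numeric value(s) in the parameter's units.
#' @examples
#' ground_truth_value("putamen", "T1", 4, variant = "without_invivo")
#' @export
ground_truth_value <- function(region, parameter, temperature,
                               coefficient_table = temperature_coefficients(),
                               variant = c("without_invivo", "with_invivo")) {
  variant <- match.arg(variant)
  row <- coefficient_table[coefficient_table$region == region &
                           coefficient_table$parameter == parameter &
                           coefficient_table$variant == variant, ]
  if (nrow(row) != 1)
    stop("no coefficient row for (", region, ", ", parameter, ", ",
         variant, ")")
  row$a + row$b * temperature
}

#' Check internal consistency of printed percentage differences
#'
#' Recomputes the 4 vs 36.5 degree percentage difference
#' `100 * (y(4) - y(36.5)) / y(36.5)` from the printed `(a, b)` of every
#' post-mortem-only (`without_invivo`) row and compares it with the printed
#' value. Because the printed coefficients are rounded (some to one
#' significant figure), an exact match cannot be expected everywhere; the
#' report therefore propagates the printed precision (half-ulp of `a` and
#' `b`, plus half-ulp of the printed percentage) into `rounding_bound_pp`
#' and flags rows whose printed precision cannot pin the percentage down
#' to 0.5 points as `rounding_limited`.
#'
#' @param coefficient_table Table as returned by
#'   [temperature_coefficients()]; an empty table yields an empty report.
#' @param tolerance_pp Flagging threshold in percentage points.
#' @return A data frame with recomputed and printed values, their absolute
#'   deviation `deviation_pp`, the propagated `rounding_bound_pp`, and
#'   logical flags `rounding_limited` and `consistent`
#'   (deviation within `max(tolerance_pp, rounding_bound_pp)`).
#' @export
validate_printed_deltas <- function(coefficient_table = temperature_coefficients(),
                                    tolerance_pp = 0.5) {
  wo <- coefficient_table[coefficient_table$variant == "without_invivo" &
                          !is.na(coefficient_table$delta_double_star), ]
  empty <- data.frame(region = character(), parameter = character(),
                      recomputed_pp = numeric(), printed_pp = numeric(),
                      deviation_pp = numeric(), rounding_bound_pp = numeric(),
                      rounding_limited = logical(), consistent = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(wo) == 0) return(empty)
  dds <- function(a, b) 100 * (b * (4 - 36.5)) / (a + b * 36.5)
  rows <- lapply(seq_len(nrow(wo)), function(i) {
    a <- wo$a[i]; b <- wo$b[i]
    ha <- wo$a_half_ulp[i]; hb <- wo$b_half_ulp[i]
    v <- dds(a, b)
    corners <- c(dds(a + ha, b + hb), dds(a + ha, b - hb),
                 dds(a - ha, b + hb), dds(a - ha, b - hb))
    # printed percentage itself is rounded to its last digit
    bound <- max(abs(corners - v)) +
      printed_half_ulp(format(wo$delta_double_star[i]))
    dev <- abs(v - wo$delta_double_star[i])
    data.frame(region = wo$region[i], parameter = wo$parameter[i],
               recomputed_pp = v, printed_pp = wo$delta_double_star[i],
               deviation_pp = dev, rounding_bound_pp = bound,
               rounding_limited = bound > tolerance_pp,
               consistent = dev <= max(tolerance_pp, bound),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

region_vocabulary <- function() {
  c("white_matter", "cerebral_cortex", "globus_pallidus", "putamen",
    "caudate_nucleus", "thalamus", "csf", "background")
}

deep_gray_subregions <- function() {
  c("globus_pallidus", "putamen", "caudate_nucleus", "thalamus")
}
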