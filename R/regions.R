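#' Partial-volume exclusion mask
#'
#' The study excluded every voxel whose tissue partial-volume fraction
#' falls below 1, keeping only pure-tissue voxels. Returns a logical mask
#' that is `TRUE` exactly where `pv >= threshold`.
#'
#' @param pv_map Array of partial-volume fractions in [0, 1].
#' @param threshold Exclusion threshold (default 1: any partial-volume
#'   contamination excludes the voxel).
#' @return Logical array of the same shape.
#' @export
exclude_partial_volume <- function(pv_map, threshold = 1.0) {
  if (any(pv_map < 0 | pv_map > 1, na.rm = TRUE))
    stop("partial-volume fractions must lie in [0, 1]")
  !is.na(pv_map) & pv_map >= threshold
}

#' Otsu threshold of a sample of values
#'
#' Otsu threshold over a grid of `n_bins` histogram bin edges: returns
#' the edge that maximises the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the two classes it induces. Class weights
#' and means are computed exactly from the values falling in each bin (not
#' from bin midpoints), so the result equals an exhaustive search over the
#' same candidate edges. Deterministic; ties resolve to the lowest
#' maximising edge.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold (a bin edge on the value scale), with attribute
#'   `eta_sq`, the fraction of total variance explained between classes
#'   (near 1 for well-separated bimodal data).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2)
    stop("Otsu threshold requires at least two distinct values")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins),
                 function(k) sum(values[bin == k]), numeric(1))
  n <- length(values)
  cw <- cumsum(counts)
  cs <- cumsum(sums)
  k_all <- seq_len(n_bins - 1)
  w0 <- cw[k_all] / n
  ok <- w0 > 0 & w0 < 1
  mu0 <- cs[k_all] / cw[k_all]
  mu1 <- (cs[n_bins] - cs[k_all]) / (n - cw[k_all])
  sigma_b <- ifelse(ok, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
  best <- max(sigma_b)
  # all edges through an empty inter-mode gap tie exactly; take their
  # centre, the conventional resolution
  ties <- which(sigma_b >= best * (1 - 1e-9))
  thr <- mean(breaks[ties + 1])
  total_var <- mean((values - mean(values))^2)
  structure(thr,
            eta_sq = if (total_var > 0) best / total_var else 0)
}

#' Otsu-based refinement of a region mask
#'
#' Thresholds the parameter values inside a mask with the Otsu method and
#' removes the voxels on the discarded side, the study's second guard
#' against partial-volume contamination (contaminated voxels form a
#' separated mode in the region's value distribution).
#'
#' Two guards handle maps without real contamination, where a forced
#' binary split would discard valid tissue: (i) if the between-class
#' variance fraction of the optimal split is below `min_eta_sq` the values
#' are considered unimodal and the full mask is kept; (ii) if the split
#' would discard more than `max_discard` of the region, it is rejected
#' with a warning and the full mask kept.
#'
#' @param map Array of parameter values.
#' @param mask Logical array, the non-empty region mask to refine.
#' @param keep_rule Which side of the threshold to keep: the `"majority"`
#'   class (default), the `"lower"` or the `"upper"` class.
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @param min_eta_sq Separability guard (between-class variance fraction).
#' @param max_discard Maximal fraction of the region the split may remove.
#' @return Refined logical mask (always a subset of `mask`).
#' @export
apply_otsu_exclusion <- function(map, mask,
                                 keep_rule = c("majority", "lower", "upper"),
                                 n_bins = 256, min_eta_sq = 0.75,
                                 max_discard = 0.5) {
  keep_rule <- match.arg(keep_rule)
  idx <- which(mask & is.finite(map))
  if (length(idx) == 0) stop("mask is empty")
  vals <- map[idx]
  if (length(unique(vals)) < 2) return(mask & is.finite(map))
  thr <- otsu_threshold(vals, n_bins = n_bins)
  if (attr(thr, "eta_sq") < min_eta_sq)
    return(mask & is.finite(map))
  lower <- vals <= thr
  keep_lower <- switch(keep_rule,
                       majority = sum(lower) >= sum(!lower),
                       lower = TRUE,
                       upper = FALSE)
  keep <- if (keep_lower) lower else !lower
  if (mean(!keep) > max_discard) {
    warning("Otsu split would discard ", round(100 * mean(!keep)),
            "% of the region; keeping the full mask")
    return(mask & is.finite(map))
  }
  out <- array(FALSE, dim = dim(mask))
  out[idx[keep]] <- TRUE
  out
}

#' Region summary of a parameter map
#'
#' Arithmetic mean and SD of the valid (finite) voxels of a map inside a
#' mask, the per-subject unit of the cohort temperature analysis.
#'
#' @param map Array of parameter values (`NA` marks invalid voxels).
#' @param mask Logical array, non-empty after exclusions.
#' @param region Region name.
#' @param parameter Parameter kind (`"T1"`, `"T2"`, ...).
#' @param subject A [subject_spec()] (or a list with `subject_id`,
#'   `cohort`, `brain_temperature`).
#' @return One-row data frame with columns `subject_id`, `cohort`,
#'   `temperature_C`, `region`, `parameter`, `mean`, `sd`, `n_voxels`.
#' @export
summarize_region <- function(map, mask, region, parameter, subject) {
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    stop("no valid voxels in region '", region, "' after exclusions")
  data.frame(subject_id = subject$subject_id, cohort = subject$cohort,
             temperature_C = subject$brain_temperature,
             region = region, parameter = parameter,
             mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
             n_voxels = length(vals), stringsAsFactors = FALSE)
}

#' Region-wise summaries of fitted maps for one subject
#'
#' Applies the two exclusion steps of the study pipeline per region and
#' parameter map -- partial-volume exclusion (fraction below
#' `pv_threshold`) followed by Otsu-threshold refinement -- and averages
#' the surviving voxels. The `deep_gray_matter` aggregate is the union of
#' the phantom's four segmented subregions (globus pallidus, putamen,
#' caudate nucleus, thalamus).
#'
#' @param maps Named list of [`voxel_map`][fit_map] objects (or plain
#'   arrays), keyed by `t1`, `t2`, `t2s`, `md`, `fa`.
#' @param phantom Output of [generate_phantom()] supplying labels and
#'   partial-volume maps.
#' @param subject A [subject_spec()].
#' @param regions Regions to summarise; `deep_gray_matter` is derived.
#' @param pv_threshold See [exclude_partial_volume()].
#' @param otsu Logical, apply the Otsu refinement step.
#' @param keep_rule Passed to [apply_otsu_exclusion()].
#' @return Data frame of [summarize_region()] rows.
#' @export
summarize_subject <- function(maps, phantom, subject,
                              regions = c("white_matter", "cerebral_cortex",
                                          "deep_gray_matter",
                                          deep_gray_subregions()),
                              pv_threshold = 1.0, otsu = TRUE,
                              keep_rule = "majority") {
  kinds <- c(t1 = "T1", t2 = "T2", t2s = "T2star", md = "MD", fa = "FA")
  elementary <- unique(unlist(lapply(regions, function(r)
    if (r == "deep_gray_matter") deep_gray_subregions() else r)))
  rows <- list()
  for (key in intersect(names(kinds), names(maps))) {
    map <- maps[[key]]
    if (inherits(map, "voxel_map")) map <- map$values
    # refined mask per elementary region; the deep-gray aggregate reuses
    # the union of its subregions' refined masks (Otsu is a per-region
    # guard -- pooling the four structures' distinct value ranges would
    # make their mixture look like contamination)
    refined <- list()
    for (region in elementary) {
      pv <- phantom$pv_maps[[region]]
      if (is.null(pv)) next
      mask <- exclude_partial_volume(pv, pv_threshold) & is.finite(map)
      if (!any(mask)) next
      if (otsu && sum(mask) >= 3)
        mask <- suppressWarnings(
          apply_otsu_exclusion(map, mask, keep_rule = keep_rule))
      refined[[region]] <- mask
    }
    for (region in regions) {
      mask <- if (region == "deep_gray_matter") {
        present <- intersect(deep_gray_subregions(), names(refined))
        if (length(present) == 0) NULL
        else Reduce(`|`, refined[present])
      } else refined[[region]]
      if (is.null(mask) || !any(mask)) next
      rows[[paste(region, key)]] <-
        summarize_region(map, mask, region, kinds[[key]], subject)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
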