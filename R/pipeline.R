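#' Configuration for the end-to-end synthetic study pipeline
#'
#' Collects every knob of the simulate - fit - aggregate - model pipeline
#' in one serializable object. A run is fully determined by its config:
#' identical configs (including `seed`) reproduce identical summary-level
#' outputs.
#'
#' @param shape Phantom dimensions (each >= 16).
#' @param n_post_mortem,n_in_vivo Cohort sizes.
#' @param temp_mean,temp_sd,temp_range Post mortem brain temperature
#'   distribution (truncated normal, degrees C).
#' @param noise_sigma Rician channel SD in signal units (m0 is 1000).
#' @param within_region_cv Within-region ground-truth variation (CV).
#' @param variant Which fitted line generates the ground truth.
#' @param parameters Parameters to simulate and fit (subset of T1, T2,
#'   T2star, MD, FA).
#' @param regions Regions to summarise.
#' @param max_voxels_per_region Per-region cap on fitted voxels (the
#'   region mean is estimated from this subsample; keeps runtimes modest).
#' @param pv_threshold,otsu,keep_rule Region-aggregation settings.
#' @param seed Run seed; every stage derives its randomness from it.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(shape = c(16, 16, 16),
                            n_post_mortem = 16, n_in_vivo = 4,
                            temp_mean = 12.7, temp_sd = 5.7,
                            temp_range = c(5.6, 28.1),
                            noise_sigma = 5,
                            within_region_cv = 0.03,
                            variant = "without_invivo",
                            parameters = c("T1", "T2", "T2star", "MD", "FA"),
                            regions = c("white_matter", "cerebral_cortex",
                                        "deep_gray_matter",
                                        deep_gray_subregions()),
                            max_voxels_per_region = 40,
                            pv_threshold = 1.0, otsu = TRUE,
                            keep_rule = "majority",
                            seed = 1L, out_dir = NULL) {
  cfg <- list(shape = as.integer(shape), n_post_mortem = n_post_mortem,
              n_in_vivo = n_in_vivo, temp_mean = temp_mean,
              temp_sd = temp_sd, temp_range = temp_range,
              noise_sigma = noise_sigma,
              within_region_cv = within_region_cv, variant = variant,
              parameters = parameters, regions = regions,
              max_voxels_per_region = max_voxels_per_region,
              pv_threshold = pv_threshold, otsu = otsu,
              keep_rule = keep_rule, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return The config (reader) or `path` (writer), invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  list(result = res,
       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full synthetic study pipeline
#'
#' Executes simulate (phantom + signals per subject), fit (relaxometry
#' and tensor maps on a per-region voxel subsample), aggregate
#' (partial-volume and Otsu exclusion, region means), and model (both
#' linear fit variants with Delta statistics), and returns a structured
#' report. Stage timings and voxel-exclusion counts are logged in the
#' report; with `out_dir` set, summaries and model tables are written as
#' CSV and the report as JSON.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`: `config`, `subjects`,
#'   `summaries`, `model_table`, `models` (nested `linear_temp_model`
#'   objects and variant comparisons), `validation` (printed-coefficient
#'   consistency report), `exclusions`, `timings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  protocol <- acquisition_protocol()
  coef_tab <- temperature_coefficients()
  timings <- list()

  need <- list(se = any(c("T2", "T1") %in% config$parameters),
               gre = "T2star" %in% config$parameters,
               ir = "T1" %in% config$parameters,
               dwi = any(c("MD", "FA") %in% config$parameters))

  n_total <- config$n_post_mortem + config$n_in_vivo
  sim <- stage("simulate+fit+aggregate", {
    rows <- list(); exclusions <- list()
    for (i in seq_len(n_total)) {
      sseed <- derive_seed(config$seed, i)
      is_pm <- i <= config$n_post_mortem
      temp <- if (is_pm)
        with_seed(sseed, rtruncnorm_reject(1, config$temp_mean,
                                           config$temp_sd,
                                           config$temp_range[1],
                                           config$temp_range[2]))
      else 36.5
      subj <- subject_spec(sprintf("%s%02d", if (is_pm) "pm" else "iv",
                                   if (is_pm) i else i - config$n_post_mortem),
                           if (is_pm) "post_mortem" else "in_vivo",
                           temp, seed = sseed, pm_range = config$temp_range)
      phantom <- generate_phantom(config$shape, subj, coef_tab,
                                  variant = config$variant,
                                  within_region_cv = config$within_region_cv)
      signals <- simulate_subject_signals(phantom, protocol,
                                          noise_sigma = config$noise_sigma,
                                          seed = derive_seed(sseed, 7))
      signals <- signals[c(names(need)[unlist(need)], "protocol")]

      mask <- sampled_region_mask(phantom, config$regions,
                                  config$pv_threshold,
                                  config$max_voxels_per_region,
                                  seed = derive_seed(sseed, 13))
      maps <- fit_map(signals, protocol, mask,
                      voxel_size = phantom$voxel_size)
      keep <- intersect(c("t1", "t2", "t2s", "md", "fa"), names(maps))
      keep <- keep[c(t1 = "T1", t2 = "T2", t2s = "T2star", md = "MD",
                     fa = "FA")[keep] %in% config$parameters]
      rows[[i]] <- summarize_subject(maps[keep], phantom, subj,
                                     regions = config$regions,
                                     pv_threshold = config$pv_threshold,
                                     otsu = config$otsu,
                                     keep_rule = config$keep_rule)
      lab <- region_labels()
      exclusions[[subj$subject_id]] <- list(
        labeled_voxels = sum(phantom$labels != lab[["background"]]),
        fitted_voxels = sum(mask),
        fit_invalid = as.list(maps$n_invalid))
    }
    list(summaries = do.call(rbind, rows), exclusions = exclusions)
  })
  timings$simulate_fit_aggregate <- sim$seconds

  mod <- stage("thermal-model", fit_cohort_models(sim$result$summaries))
  timings$thermal_model <- mod$seconds

  val <- stage("validate-coefficients", validate_printed_deltas(coef_tab))
  timings$validate <- val$seconds

  report <- structure(list(config = config,
                           summaries = sim$result$summaries,
                           model_table = mod$result,
                           models = attr(mod$result, "models"),
                           validation = val$result,
                           exclusions = sim$result$exclusions,
                           timings = timings),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$summaries,
                     file.path(config$out_dir, "region_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(report$model_table,
                     file.path(config$out_dir, "temperature_models.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), timings = timings,
           exclusions = report$exclusions),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    write_pipeline_config(config, file.path(config$out_dir, "config.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic study pipeline report\n")
  cat("  subjects:", x$config$n_post_mortem, "post mortem +",
      x$config$n_in_vivo, "in vivo; phantom",
      paste(x$config$shape, collapse = "x"), "\n")
  cat("  summaries:", nrow(x$summaries), "region-mean rows\n")
  cat("  models:", nrow(x$model_table), "fitted variants\n")
  cat("  timings (s):",
      paste(sprintf("%s=%.1f", names(x$timings), unlist(x$timings)),
            collapse = ", "), "\n")
  invisible(x)
}

# Pure-tissue mask restricted to at most max_voxels per region,
# deterministically subsampled. The region mean is then estimated from
# the subsample, which bounds fitting cost on larger phantoms.
sampled_region_mask <- function(phantom, regions, pv_threshold, max_voxels,
                                seed = 1L) {
  mask <- array(FALSE, dim = dim(phantom$labels))
  expand <- unique(unlist(lapply(regions, function(r)
    if (r == "deep_gray_matter") deep_gray_subregions() else r)))
  with_seed(seed, {
    for (region in expand) {
      pv <- phantom$pv_maps[[region]]
      if (is.null(pv)) next
      idx <- which(exclude_partial_volume(pv, pv_threshold))
      if (length(idx) > max_voxels)
        idx <- sort(sample(idx, max_voxels))
      mask[idx] <- TRUE
    }
  })
  mask
}
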