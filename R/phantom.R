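#' Region label codes used by the synthetic phantom
#'
#' @return Named integer vector mapping region names to label codes.
#' @export
region_labels <- function() {
  c(background = 0L, white_matter = 1L, cerebral_cortex = 2L,
    globus_pallidus = 3L, putamen = 4L, caudate_nucleus = 5L,
    thalamus = 6L, csf = 7L)
}

#' Subject specification for the synthetic cohort
#'
#' @param subject_id Character identifier.
#' @param cohort `"post_mortem"` or `"in_vivo"`.
#' @param brain_temperature Brain temperature in degrees C. In vivo
#'   subjects must be at exactly 36.5 (the assumed living brain
#'   temperature); post mortem temperatures must lie in `pm_range`.
#' @param seed Integer seed controlling this subject's randomness.
#' @param pm_range Allowed post mortem temperature range (degrees C).
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, cohort = c("post_mortem", "in_vivo"),
                         brain_temperature, seed = 1L,
                         pm_range = c(0, 37)) {
  cohort <- match.arg(cohort)
  if (cohort == "in_vivo" && brain_temperature != 36.5)
    stop("in vivo subjects must have brain_temperature = 36.5")
  if (cohort == "post_mortem" &&
      (brain_temperature < pm_range[1] || brain_temperature > pm_range[2]))
    stop("post mortem brain_temperature outside the configured range")
  structure(list(subject_id = as.character(subject_id), cohort = cohort,
                 brain_temperature = brain_temperature,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

# Default quantitative values for CSF, which the coefficient table does not
# cover. MD follows the known strong temperature dependence of free water
# (about 1.0e-3 mm2/s near 5 C up to 3.0e-3 mm2/s at body temperature);
# relaxation times are long and kept temperature-independent here.
csf_defaults <- function() {
  data.frame(parameter = c("T1", "T2", "T2star", "MD", "FA"),
             a = c(4000, 2000, 500, 6.8e-4, 0.02),
             b = c(0, 0, 0, 6.3e-5, 0),
             stringsAsFactors = FALSE)
}

region_parameter_value <- function(region, parameter, temperature,
                                   coefficient_table, variant) {
  if (region == "csf") {
    row <- csf_defaults()
    row <- row[row$parameter == parameter, ]
    return(row$a + row$b * temperature)
  }
  ground_truth_value(region, parameter, temperature, coefficient_table,
                     variant)
}

#' Generate a labeled brain phantom with ground-truth parameter maps
#'
#' Builds a simple geometric phantom (nested spherical compartments: a
#' cortical shell around white matter containing four deep-gray-matter
#' spheres and a central CSF cavity; not anatomically realistic) and fills
#' every labeled voxel with ground-truth T1, T2, T2*, MD and FA values
#' taken from the linear temperature models at the subject's brain
#' temperature, plus configurable Gaussian within-region variation.
#' Boundary voxels (those with a 6-neighbour of a different label) receive
#' partial-volume fractions below 1 so that the partial-volume exclusion
#' step has something to exclude.
#'
#' @param shape Integer length-3 volume dimensions, each >= 16.
#' @param subject A [subject_spec()]; its temperature and seed are used.
#' @param coefficient_table See [temperature_coefficients()].
#' @param variant Which fitted line provides the ground truth.
#' @param within_region_cv Coefficient of variation of the multiplicative
#'   Gaussian within-region variation (0 disables it).
#' @param p_factor Inversion-efficiency ground truth (2 = perfect
#'   inversion); `p_sd` adds voxel-wise Gaussian perturbation, clamped to
#'   (0, 2].
#' @param p_sd Spatial SD of the p perturbation.
#' @param m0 Equilibrium magnetisation assigned to tissue voxels (a.u.).
#' @param voxel_size Voxel edge lengths in mm.
#' @return A list with elements `labels` (3D integer array), `pv_maps`
#'   (named list of per-region partial-volume volumes), `maps` (named list
#'   with `t1`, `t2`, `t2s`, `md`, `fa`, `m0`, `p` arrays and `tensor`, a
#'   `c(shape, 6)` array of the unique tensor components in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `voxel_size`, and the `subject`.
#' @export
generate_phantom <- function(shape = c(32, 32, 32),
                             subject = subject_spec("s1", "post_mortem", 12.7),
                             coefficient_table = temperature_coefficients(),
                             variant = c("without_invivo", "with_invivo"),
                             within_region_cv = 0.03,
                             p_factor = 2, p_sd = 0,
                             m0 = 1000, voxel_size = c(1, 1, 1)) {
  variant <- match.arg(variant)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must have three axes with at least 16 voxels each")

  labels <- nested_sphere_labels(shape)
  pv_maps <- partial_volume_maps(labels)

  lab <- region_labels()
  temp <- subject$brain_temperature
  params <- c("T1", "T2", "T2star", "MD", "FA")
  maps <- list()
  with_seed(subject$seed, {
    for (pk in params) {
      vol <- array(0, dim = shape)
      for (region in setdiff(names(lab), "background")) {
        idx <- which(labels == lab[[region]])
        if (length(idx) == 0) next
        base <- region_parameter_value(region, pk, temp,
                                       coefficient_table, variant)
        vals <- rep(base, length(idx))
        if (within_region_cv > 0)
          vals <- vals * (1 + within_region_cv * stats::rnorm(length(idx)))
        if (pk == "FA") vals <- pmin(pmax(vals, 0), 1)
        else vals <- pmax(vals, 0.05 * abs(base))
        vol[idx] <- vals
      }
      maps[[pk]] <- vol
    }
    p_map <- array(0, dim = shape)
    tissue <- which(labels != lab[["background"]])
    p_vals <- rep(p_factor, length(tissue))
    if (p_sd > 0)
      p_vals <- pmin(pmax(p_vals + p_sd * stats::rnorm(length(tissue)),
                          1e-3), 2)
    p_map[tissue] <- p_vals
  })
  m0_map <- array(0, dim = shape)
  m0_map[labels != lab[["background"]]] <- m0

  tensor <- tensor_volume_from_md_fa(maps$MD, maps$FA, labels)

  list(labels = labels, pv_maps = pv_maps,
       maps = list(t1 = maps$T1, t2 = maps$T2, t2s = maps$T2star,
                   md = maps$MD, fa = maps$FA, m0 = m0_map, p = p_map,
                   tensor = tensor),
       voxel_size = voxel_size, subject = subject)
}

# Nested spherical compartments in normalised coordinates.
nested_sphere_labels <- function(shape) {
  lab <- region_labels()
  cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
  X <- array(rep(cx, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)
  r <- sqrt(X^2 + Y^2 + Z^2)

  labels <- array(lab[["background"]], dim = shape)
  labels[r <= 0.95] <- lab[["cerebral_cortex"]]
  labels[r <= 0.72] <- lab[["white_matter"]]
  centers <- list(globus_pallidus = c(0.36, 0.36, 0),
                  putamen = c(-0.36, 0.36, 0),
                  caudate_nucleus = c(0.36, -0.36, 0),
                  thalamus = c(-0.36, -0.36, 0))
  for (region in names(centers)) {
    cc <- centers[[region]]
    d <- sqrt((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2)
    labels[d <= 0.22] <- lab[[region]]
  }
  labels[r <= 0.12] <- lab[["csf"]]
  labels
}

# Per-region partial volume fraction volumes: 1 in the interior, shared
# between the two touching regions (0.5 each) at 6-neighbourhood label
# boundaries, 0 elsewhere.
partial_volume_maps <- function(labels) {
  shape <- dim(labels)
  boundary <- array(FALSE, dim = shape)
  shift_differs <- function(axis, by) {
    idx_from <- lapply(shape, seq_len)
    idx_to <- idx_from
    n <- shape[axis]
    if (by == 1) { idx_from[[axis]] <- 1:(n - 1); idx_to[[axis]] <- 2:n }
    else { idx_from[[axis]] <- 2:n; idx_to[[axis]] <- 1:(n - 1) }
    diff <- do.call(`[`, c(list(labels), idx_from)) !=
      do.call(`[`, c(list(labels), idx_to))
    out <- array(FALSE, dim = shape)
    out <- do.call(`[<-`, c(list(out), idx_from, list(diff)))
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    boundary <- boundary | shift_differs(axis, by)

  lab <- region_labels()
  pv <- list()
  for (region in setdiff(names(lab), "background")) {
    vol <- array(0, dim = shape)
    inside <- labels == lab[[region]]
    vol[inside] <- 1
    vol[inside & boundary] <- 0.5
    pv[[region]] <- vol
  }
  # the complementary 0.5 at a boundary voxel belongs to the neighbouring
  # region; fractions therefore sum to at most 1 per voxel
  pv
}

# Axially symmetric tensor with prescribed MD and FA. With
# eigenvalues md*(1+2*alpha), md*(1-alpha), md*(1-alpha) the FA equals
# 3*alpha/sqrt(3+6*alpha^2), inverted as alpha = fa/sqrt(3-2*fa^2).
tensor_from_md_fa <- function(md, fa, axis = c(1, 0, 0)) {
  fa <- min(max(fa, 0), 1)
  alpha <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * alpha)
  l2 <- md * (1 - alpha)
  e1 <- axis / sqrt(sum(axis^2))
  D <- l2 * diag(3) + (l1 - l2) * (e1 %o% e1)
  (D + t(D)) / 2
}

# Per-region fixed principal axes; white matter along x, deep structures
# tilted so rotation-invariance is exercised.
region_axes <- function() {
  list(white_matter = c(1, 0, 0), cerebral_cortex = c(0, 1, 0),
       globus_pallidus = c(1, 1, 0), putamen = c(1, 0, 1),
       caudate_nucleus = c(0, 1, 1), thalamus = c(1, 1, 1),
       csf = c(1, 0, 0))
}

tensor_volume_from_md_fa <- function(md_vol, fa_vol, labels) {
  shape <- dim(md_vol)
  tensor <- array(0, dim = c(shape, 6))
  lab <- region_labels()
  axes <- region_axes()
  nvox <- prod(shape)
  comp_idx <- function(k) ((k - 1) * nvox)
  for (region in setdiff(names(lab), "background")) {
    idx <- which(labels == lab[[region]])
    if (length(idx) == 0) next
    axis <- axes[[region]]
    for (i in idx) {
      D <- tensor_from_md_fa(md_vol[i], fa_vol[i], axis)
      tensor[i + comp_idx(1)] <- D[1, 1]
      tensor[i + comp_idx(2)] <- D[2, 2]
      tensor[i + comp_idx(3)] <- D[3, 3]
      tensor[i + comp_idx(4)] <- D[1, 2]
      tensor[i + comp_idx(5)] <- D[1, 3]
      tensor[i + comp_idx(6)] <- D[2, 3]
    }
  }
  tensor
}

#' Simulate the full multi-contrast acquisition for one phantom
#'
#' Evaluates the IR-SE, multi-echo SE, multi-echo GRE and diffusion
#' forward models at every voxel of a phantom and applies Rician noise.
#' All outputs are magnitude images, as produced by a scanner; the signed
#' IR-SE polarity information is deliberately discarded (the fitting side
#' restores it).
#'
#' @param phantom Output of [generate_phantom()].
#' @param protocol An [acquisition_protocol()].
#' @param noise_sigma Rician channel SD in signal units (0 = noiseless).
#' @param seed Integer seed for the noise.
#' @return A list of 4D arrays `ir`, `se`, `gre` (last axis = echo index)
#'   and `dwi` (b0 volumes first, then one volume per direction), plus the
#'   `protocol`.
#' @export
simulate_subject_signals <- function(phantom, protocol = acquisition_protocol(),
                                     noise_sigma = 0, seed = 1L) {
  shape <- dim(phantom$labels)
  maps <- phantom$maps
  tissue <- maps$m0 > 0
  safe <- function(x) ifelse(tissue, x, 1)  # avoid 0/0 in background

  ir <- array(0, dim = c(shape, length(protocol$ti_list)))
  for (k in seq_along(protocol$ti_list)) {
    s <- maps$m0 * exp(-protocol$ir_te / safe(maps$t2)) *
      (1 - maps$p * exp(-protocol$ti_list[k] / safe(maps$t1)) +
         exp(-protocol$ir_tr / safe(maps$t1)))
    ir[, , , k] <- ifelse(tissue, s, 0)
  }
  se <- array(0, dim = c(shape, length(protocol$se_te_list)))
  for (k in seq_along(protocol$se_te_list))
    se[, , , k] <- ifelse(tissue,
                          maps$m0 * exp(-protocol$se_te_list[k] / safe(maps$t2)),
                          0)
  gre <- array(0, dim = c(shape, length(protocol$gre_te_list)))
  for (k in seq_along(protocol$gre_te_list))
    gre[, , , k] <- ifelse(tissue,
                           maps$m0 * exp(-protocol$gre_te_list[k] / safe(maps$t2s)),
                           0)

  nvol <- protocol$n_b0 + protocol$n_directions
  dwi <- array(0, dim = c(shape, nvol))
  for (k in seq_len(protocol$n_b0)) dwi[, , , k] <- maps$m0
  tens <- matrix(phantom$maps$tensor, ncol = 6)
  g <- protocol$gradient_set
  for (k in seq_len(protocol$n_directions)) {
    gk <- g[k, ]
    adc <- tens[, 1] * gk[1]^2 + tens[, 2] * gk[2]^2 + tens[, 3] * gk[3]^2 +
      2 * (tens[, 4] * gk[1] * gk[2] + tens[, 5] * gk[1] * gk[3] +
             tens[, 6] * gk[2] * gk[3])
    vol <- as.numeric(maps$m0) * exp(-protocol$b_value * adc)
    dwi[, , , protocol$n_b0 + k] <- array(vol, dim = shape)
  }

  with_seed(seed, {
    ir <- add_rician_noise(ir, noise_sigma)
    se <- add_rician_noise(se, noise_sigma)
    gre <- add_rician_noise(gre, noise_sigma)
    dwi <- add_rician_noise(dwi, noise_sigma)
  })
  list(ir = ir, se = se, gre = gre, dwi = dwi, protocol = protocol)
}
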