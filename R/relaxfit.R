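#' Two-parameter mono-exponential decay fit
#'
#' Estimates `(s0, t2)` of `s(TE) = s0 * exp(-TE / t2)` from multi-echo
#' magnitude data by Levenberg-Marquardt least squares, initialised from
#' the log-linear regression of `log(signal)` on TE. Used for both T2
#' (spin-echo) and T2* (gradient-echo) mapping, which differ only in their
#' echo lists.
#'
#' Voxels with fewer than three positive echoes or with a non-decaying
#' signal (log-linear slope >= 0) are flagged invalid rather than raising
#' an error, so that map-level drivers can record a sentinel and move on.
#'
#' @param signals Per-echo magnitudes (non-negative).
#' @param te_list Echo times (ms), same length as `signals`.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return A list: `s0`, `t2` (NA when invalid), `valid`, and
#'   `diagnostics` with `residual_norm`, `converged`, `iterations`.
#' @examples
#' te <- c(9.8, 19.6, 29.4, 39.2, 49, 58.8)
#' fit_monoexp(simulate_monoexp_signal(1000, 80, te), te)
#' @export
fit_monoexp <- function(signals, te_list,
                        control = minpack.lm::nls.lm.control(
                          ptol = 1e-10, ftol = 1e-10, maxiter = 500)) {
  if (length(signals) != length(te_list))
    stop("signals and te_list must have equal length")
  if (length(signals) < 3)
    stop("at least 3 echoes are required")
  if (any(signals < 0)) stop("magnitude signals must be non-negative")
  invalid <- list(s0 = NA_real_, t2 = NA_real_, valid = FALSE,
                  diagnostics = list(residual_norm = NA_real_,
                                     converged = FALSE, iterations = 0L))
  pos <- signals > 0
  if (sum(pos) < 3) return(invalid)
  init <- stats::lm.fit(cbind(1, te_list[pos]), log(signals[pos]))$coefficients
  if (!is.finite(init[2]) || init[2] >= -1e-12) return(invalid)
  start <- c(s0 = exp(init[1]), t2 = -1 / init[2])
  resid_fun <- function(par) par[1] * exp(-te_list / par[2]) - signals
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun, control = control)
  est <- fit$par
  if (!is.finite(est[2]) || est[2] <= 0) return(invalid)
  list(s0 = unname(est[1]), t2 = unname(est[2]), valid = TRUE,
       diagnostics = list(residual_norm = sqrt(sum(fit$fvec^2)),
                          converged = fit$info %in% 1:4,
                          iterations = fit$niter))
}

#' Three-parameter inversion-recovery T1 fit with polarity restoration
#'
#' Estimates `(m0, p, t1)` of the IR-SE model
#' `S = m0 * exp(-TE/T2) * (1 - p * exp(-TI/T1) + exp(-TR/T1))`
#' from a multi-TI series, holding TE, TR and the voxel's previously
#' fitted T2 fixed. The factor p absorbs B1 errors of the inversion pulse
#' (p = 2 is a perfect inversion).
#'
#' Magnitude data lose the sign of the recovery curve; with
#' `signed = FALSE` (the default, matching scanner data) the fit restores
#' polarity by negating the first k inversion times for every k = 0..n,
#' fitting each candidate, and keeping the lowest-residual fit.
#'
#' Estimates are unconstrained during optimisation; a voxel is flagged
#' invalid when `t1 <= 0`, `p <= 0`, or `p > 2 + p_slack` (the slack above
#' the physical bound avoids invalidating half of all voxels when noise
#' scatters estimates around a perfect inversion).
#'
#' @param signals Per-TI signals: magnitudes (`signed = FALSE`) or signed
#'   values (`signed = TRUE`).
#' @param ti_list Inversion times (ms), >= 4 values.
#' @param te,tr Echo and repetition time (ms).
#' @param t2_voxel The voxel's T2 (ms) from [fit_monoexp()]; a missing or
#'   non-positive value flags the voxel invalid.
#' @param signed Whether `signals` retain their true sign.
#' @param p_slack Validity slack above p = 2.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return A list: `m0`, `p_factor`, `t1` (NA when invalid), `valid`,
#'   `n_restored` (how many leading TIs were negated), and `diagnostics`.
#' @examples
#' ti <- c(30, 80, 200, 400, 700, 1200)
#' s <- simulate_ir_se_signal(1000, 2, 600, 80, ti, te = 12, tr = 7060)
#' fit_t1_ir(abs(s), ti, te = 12, tr = 7060, t2_voxel = 80)
#' @export
fit_t1_ir <- function(signals, ti_list, te, tr, t2_voxel,
                      signed = FALSE, p_slack = 0.5,
                      control = minpack.lm::nls.lm.control(
                        ptol = 1e-10, ftol = 1e-10, maxiter = 500)) {
  if (length(signals) != length(ti_list))
    stop("signals and ti_list must have equal length")
  if (length(ti_list) < 4)
    stop("at least 4 inversion times are required")
  invalid <- list(m0 = NA_real_, p_factor = NA_real_, t1 = NA_real_,
                  valid = FALSE, n_restored = NA_integer_,
                  diagnostics = list(residual_norm = NA_real_,
                                     converged = FALSE, iterations = 0L))
  if (!is.finite(t2_voxel) || t2_voxel <= 0) return(invalid)
  f <- exp(-te / t2_voxel)
  n <- length(signals)
  ks <- if (signed) 0L else 0:n

  best <- NULL
  for (k in ks) {
    y <- signals
    if (k > 0) y[seq_len(k)] <- -abs(y[seq_len(k)])
    ti_null <- ti_list[which.min(abs(y))]
    t1_init <- min(max(ti_null / log(2), 10), 5000)
    start <- c(m0 = max(abs(y)) / f, p = 2, t1 = t1_init)
    resid_fun <- function(par)
      par[1] * f * (1 - par[2] * exp(-ti_list / par[3]) +
                      exp(-tr / par[3])) - y
    fit <- try(minpack.lm::nls.lm(par = start, fn = resid_fun,
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (!is.finite(rn)) next
    if (is.null(best) || rn < best$rn)
      best <- list(fit = fit, rn = rn, k = k)
  }
  if (is.null(best)) return(invalid)
  est <- best$fit$par
  valid <- is.finite(est[3]) && est[3] > 0 &&
    is.finite(est[2]) && est[2] > 0 && est[2] <= 2 + p_slack
  if (!valid) return(invalid)
  list(m0 = unname(est[1]), p_factor = unname(est[2]), t1 = unname(est[3]),
       valid = TRUE, n_restored = as.integer(best$k),
       diagnostics = list(residual_norm = best$rn,
                          converged = best$fit$info %in% 1:4,
                          iterations = best$fit$niter))
}

new_voxel_map <- function(values, parameter_kind, units,
                          voxel_size = c(1, 1, 1)) {
  structure(list(values = values, parameter_kind = parameter_kind,
                 units = units, voxel_size = voxel_size),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("Voxel map:", x$parameter_kind, "(", x$units, ")\n")
  cat("  dims:", paste(dim(x$values), collapse = " x "),
      "; valid voxels:", length(v), "\n")
  if (length(v))
    cat("  range:", format(min(v), digits = 4), "-",
        format(max(v), digits = 4), "\n")
  invisible(x)
}

#' Voxel-wise parameter mapping over a mask
#'
#' Applies the relaxometry fits (and, when diffusion data are present,
#' the tensor fit) to every voxel of a mask and assembles parameter maps.
#' Invalid voxels are recorded as `NA` and excluded from downstream
#' statistics. The SE series must be fitted before (or together with) the
#' IR series, because the T1 model consumes the voxel's T2.
#'
#' @param signals List of 4D signal arrays as returned by
#'   [simulate_subject_signals()] (`ir`, `se`, `gre`, `dwi`); any subset
#'   may be present, but `ir` requires `se`.
#' @param protocol The [acquisition_protocol()] the signals follow.
#' @param mask Logical 3D array selecting voxels to fit; an empty mask
#'   yields all-`NA` maps.
#' @param voxel_size Voxel size recorded on the output maps.
#' @return A named list of [`voxel_map`][fit_map] objects among `t1`,
#'   `m0`, `p`, `t2`, `t2s`, `md`, `fa`, plus `n_invalid`, a named count
#'   of invalid voxels per map.
#' @export
fit_map <- function(signals, protocol, mask, voxel_size = c(1, 1, 1)) {
  shape <- dim(mask)
  idx <- which(mask)
  nvox <- prod(shape)
  blank <- function() array(NA_real_, dim = shape)
  out <- list()
  n_invalid <- c()

  flat <- function(vol4d) matrix(vol4d, nrow = nvox)

  t2_map <- NULL
  if (!is.null(signals$se)) {
    m <- flat(signals$se)
    t2_map <- blank(); s0_map <- blank()
    bad <- 0L
    for (i in idx) {
      f <- fit_monoexp(m[i, ], protocol$se_te_list)
      if (f$valid) { t2_map[i] <- f$t2; s0_map[i] <- f$s0 }
      else bad <- bad + 1L
    }
    out$t2 <- new_voxel_map(t2_map, "T2", "ms", voxel_size)
    n_invalid["t2"] <- bad
  }
  if (!is.null(signals$gre)) {
    m <- flat(signals$gre)
    t2s_map <- blank()
    bad <- 0L
    for (i in idx) {
      f <- fit_monoexp(m[i, ], protocol$gre_te_list)
      if (f$valid) t2s_map[i] <- f$t2 else bad <- bad + 1L
    }
    out$t2s <- new_voxel_map(t2s_map, "T2star", "ms", voxel_size)
    n_invalid["t2s"] <- bad
  }
  if (!is.null(signals$ir)) {
    if (is.null(t2_map))
      stop("the IR T1 fit requires the SE series (for voxel-wise T2)")
    m <- flat(signals$ir)
    t1_map <- blank(); m0_map <- blank(); p_map <- blank()
    bad <- 0L
    for (i in idx) {
      f <- fit_t1_ir(m[i, ], protocol$ti_list, protocol$ir_te,
                     protocol$ir_tr, t2_map[i])
      if (f$valid) {
        t1_map[i] <- f$t1; m0_map[i] <- f$m0; p_map[i] <- f$p_factor
      } else bad <- bad + 1L
    }
    out$t1 <- new_voxel_map(t1_map, "T1", "ms", voxel_size)
    out$m0 <- new_voxel_map(m0_map, "M0", "a.u.", voxel_size)
    out$p <- new_voxel_map(p_map, "p", "dimensionless", voxel_size)
    n_invalid["t1"] <- bad
  }
  if (!is.null(signals$dwi)) {
    dti <- fit_dti_map(signals$dwi, protocol, mask, voxel_size)
    out$md <- dti$md
    out$fa <- dti$fa
    n_invalid["dti"] <- dti$n_invalid
  }
  out$n_invalid <- n_invalid
  out
}
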