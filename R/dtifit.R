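#' Log-linear diffusion tensor fit
#'
#' Estimates the six unique components of the diffusion tensor and the
#' unweighted signal s0 by ordinary least squares of the log-signals on
#' the design matrix `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy,
#' -2b gx gz, -2b gy gz]` (the standard unweighted log-linear fit).
#' All b = 0 volumes are averaged into a single reference measurement
#' before fitting.
#'
#' @param signals Signal vector, one value per volume.
#' @param b_values b-value per volume (s/mm2); zeros mark the unweighted
#'   volumes.
#' @param directions n x 3 matrix of gradient directions (rows for b = 0
#'   volumes are ignored).
#' @param signal_floor Non-positive signals are clamped to
#'   `signal_floor * max(signals)` and the voxel flagged `clamped`.
#' @return A list: `tensor` (symmetric 3 x 3, mm2/s), `s0`, `eigenvalues`
#'   (non-increasing), `clamped`, `negative_eigenvalues` flags.
#' @examples
#' prot <- acquisition_protocol()
#' D <- diag(c(1.5e-3, 3e-4, 3e-4))
#' s <- c(rep(1000, 3), simulate_dwi_signal(1000, D, 2000,
#'                                          prot$gradient_set))
#' fit_tensor(s, c(rep(0, 3), rep(2000, 64)),
#'            rbind(matrix(0, 3, 3), prot$gradient_set))$eigenvalues
#' @export
fit_tensor <- function(signals, b_values, directions,
                       signal_floor = 1e-6) {
  directions <- as.matrix(directions)
  if (length(signals) != length(b_values) ||
      nrow(directions) != length(signals))
    stop("signals, b_values and directions must agree in length")
  is_b0 <- b_values == 0
  if (!any(is_b0)) stop("at least one b = 0 volume is required")
  if (sum(!is_b0) < 6)
    stop("at least 6 diffusion-weighted volumes are required")

  clamped <- FALSE
  floor_val <- signal_floor * max(signals)
  if (any(signals <= 0)) {
    signals <- pmax(signals, floor_val)
    clamped <- TRUE
  }

  s0_mean <- mean(signals[is_b0])
  dw_idx <- which(!is_b0)
  g <- directions[dw_idx, , drop = FALSE]
  b <- b_values[dw_idx]
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  X <- rbind(c(1, rep(0, 6)), X)
  y <- c(log(s0_mean), log(signals[dw_idx]))
  qrX <- qr(X)
  if (qrX$rank < 7)
    stop("rank-deficient design: gradient directions do not span the ",
         "six tensor components (rank ", qrX$rank, " of 7)")
  beta <- qr.coef(qrX, y)
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(tensor = D, s0 = exp(beta[1]), eigenvalues = ev,
       clamped = clamped, negative_eigenvalues = any(ev < 0))
}

tensor_eigenvalues <- function(tensor) {
  sort(eigen(as.matrix(tensor), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Mean diffusivity of a tensor
#'
#' MD = trace(D) / 3 = (lambda1 + lambda2 + lambda3) / 3.
#'
#' @param tensor Symmetric 3 x 3 tensor, or a length-3 eigenvalue vector.
#' @return Mean diffusivity (mm2/s).
#' @export
compute_md <- function(tensor) {
  ev <- if (is.matrix(tensor)) diag(tensor) else tensor
  if (length(ev) != 3) stop("expected a 3 x 3 tensor or 3 eigenvalues")
  sum(ev) / 3
}

#' Fractional anisotropy of a tensor
#'
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||, computed on eigenvalues
#' with negative values clamped to zero and the result clamped to [0, 1].
#' A zero tensor has no defined anisotropy and returns `NA`.
#'
#' @param tensor Symmetric 3 x 3 tensor, or a length-3 eigenvalue vector.
#' @return FA in [0, 1], or `NA` for a zero tensor.
#' @export
compute_fa <- function(tensor) {
  ev <- if (is.matrix(tensor)) tensor_eigenvalues(tensor) else sort(tensor,
                                                                    decreasing = TRUE)
  if (length(ev) != 3) stop("expected a 3 x 3 tensor or 3 eigenvalues")
  ev <- pmax(ev, 0)
  if (all(ev == 0)) return(NA_real_)
  md <- mean(ev)
  fa <- sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
  min(max(fa, 0), 1)
}

#' Voxel-wise tensor fitting over a mask
#'
#' Runs [fit_tensor()] in every mask voxel of a 4D diffusion volume (b0
#' volumes first, per the protocol) and derives MD and FA maps. Voxels
#' whose fit degenerates (all-zero signal) are recorded as `NA`.
#'
#' @param dwi 4D array `c(shape, n_b0 + n_directions)`.
#' @param protocol The [acquisition_protocol()].
#' @param mask Logical 3D array.
#' @param voxel_size Voxel size recorded on the output maps.
#' @return List with `md` and `fa` [`voxel_map`][fit_map] objects,
#'   `tensor` (`c(shape, 6)` array: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) and
#'   `n_invalid`.
#' @export
fit_dti_map <- function(dwi, protocol, mask, voxel_size = c(1, 1, 1)) {
  shape <- dim(mask)
  nvox <- prod(shape)
  m <- matrix(dwi, nrow = nvox)
  bvals <- c(rep(0, protocol$n_b0), rep(protocol$b_value,
                                        protocol$n_directions))
  dirs <- rbind(matrix(0, protocol$n_b0, 3), protocol$gradient_set)
  md_map <- array(NA_real_, dim = shape)
  fa_map <- array(NA_real_, dim = shape)
  tensor <- array(NA_real_, dim = c(shape, 6))
  bad <- 0L
  for (i in which(mask)) {
    sig <- m[i, ]
    if (all(sig <= 0)) { bad <- bad + 1L; next }
    fit <- try(fit_tensor(sig, bvals, dirs), silent = TRUE)
    if (inherits(fit, "try-error")) { bad <- bad + 1L; next }
    md_map[i] <- compute_md(fit$eigenvalues)
    fa_map[i] <- compute_fa(fit$eigenvalues)
    D <- fit$tensor
    tensor[i + nvox * 0:5] <- c(D[1, 1], D[2, 2], D[3, 3],
                                D[1, 2], D[1, 3], D[2, 3])
  }
  list(md = new_voxel_map(md_map, "MD", "mm2/s", voxel_size),
       fa = new_voxel_map(fa_map, "FA", "dimensionless", voxel_size),
       tensor = tensor, n_invalid = bad)
}
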