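#' Acquisition protocol for the multi-contrast quantitative MRI study
#'
#' Bundles the sequence timing constants of the four quantitative
#' acquisitions used throughout the package: an inversion-recovery
#' spin-echo (IR-SE) series for T1, a multi-echo spin-echo (SE) series for
#' T2, a multi-echo gradient-echo (GRE) series for T2*, and a single-shell
#' diffusion-weighted series for the diffusion tensor. Defaults are the
#' 3 T in situ study protocol: six inversion times, twelve SE echoes,
#' twelve GRE echoes, and b = 2000 s/mm2 with 64 isotropically distributed
#' directions plus three b = 0 volumes.
#'
#' The third SE echo is 29.4 ms, continuing the 9.8 ms echo spacing of the
#' printed list.
#'
#' @param ti_list Inversion times TI in ms, strictly increasing.
#' @param ir_te,ir_tr IR-SE echo and repetition time (ms).
#' @param se_te_list Spin-echo echo times (ms).
#' @param se_tr Spin-echo repetition time (ms).
#' @param gre_te_list Gradient-echo echo times (ms).
#' @param gre_tr Gradient-echo repetition time (ms).
#' @param b_value Diffusion weighting (s/mm2).
#' @param n_directions Number of diffusion gradient directions (>= 6).
#' @param n_b0 Number of unweighted (b = 0) volumes.
#' @param dwi_te,dwi_tr Diffusion sequence echo/repetition time (ms).
#' @param gradient_set Optional n_directions x 3 matrix of unit gradient
#'   vectors; defaults to a deterministic spherical Fibonacci set.
#' @return An object of class `acquisition_protocol` (a validated list).
#' @examples
#' prot <- acquisition_protocol()
#' prot$ti_list
#' @export
acquisition_protocol <- function(ti_list = c(30, 80, 200, 400, 700, 1200),
                                 ir_te = 12, ir_tr = 7060,
                                 se_te_list = c(9.8, 19.6, 29.4, 39.2, 49.0,
                                                58.8, 68.6, 78.4, 88.2, 98,
                                                107.8, 117.6),
                                 se_tr = 5720,
                                 gre_te_list = c(5.79, 10.34, 14.40, 18.46,
                                                 22.52, 26.58, 30.64, 34.70,
                                                 38.76, 42.82, 46.88, 50.94),
                                 gre_tr = 68,
                                 b_value = 2000,
                                 n_directions = 64,
                                 n_b0 = 3,
                                 dwi_te = 109, dwi_tr = 18700,
                                 gradient_set = NULL) {
  if (is.null(gradient_set)) {
    gradient_set <- fibonacci_directions(n_directions)
  }
  gradient_set <- as.matrix(gradient_set)
  prot <- structure(
    list(ti_list = as.numeric(ti_list), ir_te = ir_te, ir_tr = ir_tr,
         se_te_list = as.numeric(se_te_list), se_tr = se_tr,
         gre_te_list = as.numeric(gre_te_list), gre_tr = gre_tr,
         b_value = b_value, n_directions = nrow(gradient_set), n_b0 = n_b0,
         dwi_te = dwi_te, dwi_tr = dwi_tr, gradient_set = gradient_set),
    class = "acquisition_protocol")
  validate_protocol(prot)
  prot
}

validate_protocol <- function(prot) {
  times <- c(prot$ti_list, prot$ir_te, prot$ir_tr, prot$se_te_list,
             prot$se_tr, prot$gre_te_list, prot$gre_tr, prot$dwi_te,
             prot$dwi_tr)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("all protocol times must be strictly positive")
  if (is.unsorted(prot$ti_list, strictly = TRUE))
    stop("ti_list must be strictly increasing")
  if (prot$ir_te >= prot$ir_tr || max(prot$se_te_list) >= prot$se_tr ||
      max(prot$gre_te_list) >= prot$gre_tr || prot$dwi_te >= prot$dwi_tr)
    stop("TE must be smaller than TR for every sequence")
  if (prot$b_value <= 0) stop("b_value must be positive")
  if (prot$n_directions < 6)
    stop("at least 6 gradient directions are required for a tensor fit")
  if (prot$n_b0 < 1) stop("at least one b = 0 volume is required")
  norms <- sqrt(rowSums(prot$gradient_set^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("gradient vectors must be unit-norm within 1e-6")
  invisible(prot)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Acquisition protocol\n")
  cat("  IR-SE : TI =", paste(x$ti_list, collapse = ", "),
      "ms; TE =", x$ir_te, "ms; TR =", x$ir_tr, "ms\n")
  cat("  SE    :", length(x$se_te_list), "echoes,",
      min(x$se_te_list), "-", max(x$se_te_list), "ms; TR =", x$se_tr, "ms\n")
  cat("  GRE   :", length(x$gre_te_list), "echoes,",
      min(x$gre_te_list), "-", max(x$gre_te_list), "ms; TR =", x$gre_tr,
      "ms\n")
  cat("  DWI   : b =", x$b_value, "s/mm2,", x$n_directions, "directions +",
      x$n_b0, "b0; TE =", x$dwi_te, "ms; TR =", x$dwi_tr, "ms\n")
  invisible(x)
}

#' Deterministic, approximately isotropic unit directions
#'
#' Spherical Fibonacci lattice on the unit sphere, the standard deterministic
#' construction for well-spread diffusion-encoding direction sets.
#'
#' @param n Number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Read and write FSL-dialect gradient tables
#'
#' `write_bvals_bvecs()` writes the `bvals` (one row of b-values) and
#' `bvecs` (three rows: x, y, z components) plain-text files that
#' diffusion tools expect; `read_bvals_bvecs()` reads them back.
#'
#' @param protocol An [acquisition_protocol()]; b0 volumes come first.
#' @param bval_path,bvec_path Output/input file paths.
#' @return For the reader, a list with `bvals` (numeric vector) and
#'   `bvecs` (n x 3 matrix).
#' @export
write_bvals_bvecs <- function(protocol, bval_path, bvec_path) {
  bvals <- c(rep(0, protocol$n_b0),
             rep(protocol$b_value, protocol$n_directions))
  bvecs <- rbind(matrix(0, protocol$n_b0, 3), protocol$gradient_set)
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1, function(row)
    paste(format(row, digits = 15), collapse = " ")), bvec_path)
  invisible(list(bvals = bvals, bvecs = bvecs))
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  if (length(bvec_rows) != 3)
    stop("bvec file must contain exactly three rows (x, y, z)")
  bvecs <- t(do.call(rbind, bvec_rows))
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes")
  list(bvals = bvals, bvecs = bvecs)
}
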