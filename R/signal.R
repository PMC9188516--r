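#' Inversion-recovery spin-echo signal model
#'
#' Signed signal of an IR-SE acquisition with a finite repetition time and
#' an inversion-efficiency factor p absorbing B1 errors of the 180-degree
#' inversion pulse (p = 2 is a perfect inversion, p < 2 an imperfect one):
#'
#' \deqn{S = M_0 \exp(-TE/T_2)\,\bigl(1 - p\,e^{-TI/T_1} + e^{-TR/T_1}\bigr)}
#'
#' @param m0 Equilibrium magnetisation (arbitrary units, >= 0).
#' @param p_factor Inversion-efficiency factor (dimensionless).
#' @param t1,t2 Longitudinal and transverse relaxation times (ms, > 0).
#' @param ti Inversion time (ms, > 0); may be a vector.
#' @param te,tr Echo and repetition time (ms, > 0).
#' @return The signed model signal, same length as `ti`.
#' @examples
#' simulate_ir_se_signal(1000, 2, 600, 80, ti = c(30, 400, 1200),
#'                       te = 12, tr = 7060)
#' @export
simulate_ir_se_signal <- function(m0, p_factor, t1, t2, ti, te, tr) {
  if (any(c(t1, t2, ti, te, tr) <= 0) || any(!is.finite(c(t1, t2))))
    stop("relaxation times and sequence times must be strictly positive")
  if (any(m0 < 0)) stop("m0 must be non-negative")
  m0 * exp(-te / t2) * (1 - p_factor * exp(-ti / t1) + exp(-tr / t1))
}

#' Mono-exponential decay signal model
#'
#' Forward model of the two-parameter single-decay fit used for T2
#' (spin-echo) and T2* (gradient-echo) mapping: `s0 * exp(-te / t2)`.
#'
#' @param s0 Signal at TE = 0 (>= 0).
#' @param t2_or_t2s Decay constant T2 or T2* (ms, > 0).
#' @param te Echo time(s) (ms, >= 0).
#' @return The model signal, same length as `te`.
#' @export
simulate_monoexp_signal <- function(s0, t2_or_t2s, te) {
  if (any(s0 < 0)) stop("s0 must be non-negative")
  if (any(t2_or_t2s <= 0)) stop("decay constant must be strictly positive")
  if (any(te < 0)) stop("te must be non-negative")
  s0 * exp(-te / t2_or_t2s)
}

#' Diffusion tensor signal model
#'
#' Single-shell mono-exponential tensor model
#' `s0 * exp(-b * g' D g)` for a symmetric positive semidefinite tensor D.
#'
#' @param s0 Unweighted signal (>= 0).
#' @param tensor Symmetric 3 x 3 diffusion tensor (mm2/s).
#' @param b_value Diffusion weighting (s/mm2, >= 0).
#' @param direction Unit gradient vector (length 3), or an n x 3 matrix.
#' @return Signal value(s), one per direction.
#' @export
simulate_dwi_signal <- function(s0, tensor, b_value, direction) {
  tensor <- as.matrix(tensor)
  if (any(dim(tensor) != c(3, 3)) || max(abs(tensor - t(tensor))) > 1e-12)
    stop("tensor must be a symmetric 3 x 3 matrix")
  if (b_value < 0) stop("b_value must be non-negative")
  g <- if (is.matrix(direction)) direction else matrix(direction, 1, 3)
  if (b_value > 0) {
    norms <- sqrt(rowSums(g^2))
    if (any(abs(norms - 1) > 1e-6))
      stop("gradient directions must be unit-norm")
  }
  adc <- rowSums((g %*% tensor) * g)
  as.numeric(s0 * exp(-b_value * adc))
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude MR images carry Rician noise: the modulus of the complex
#' signal after independent zero-mean Gaussian perturbations of the real
#' and imaginary channels. The noiseless signal is placed on the real
#' axis, so `sigma = 0` returns `abs(signal)`.
#'
#' @param signal Noiseless (possibly signed) signal; any shape.
#' @param sigma Gaussian channel SD (>= 0), in signal units.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Noisy magnitude values with the shape of `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(abs(signal))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- length(signal)
  noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
  noisy
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run code under a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  code
}
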