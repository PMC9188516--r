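# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed-form normal equations for OLS, an
# explicit split-and-measure loop for Otsu, and direct eigenvalue
# arithmetic for tensor invariants.

# Closed-form simple OLS with t-based CIs, adjusted R2 and the slope test.
ols_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  b <- sxy / sxx
  a <- ybar - b * xbar
  resid <- y - a - b * x
  rss <- sum(resid^2)
  syy <- sum((y - ybar)^2)
  s2 <- rss / (n - 2)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  r2 <- 1 - rss / syy
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  tstat <- b / se_b
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(a = a, b = b, se_a = se_a, se_b = se_b,
       ci_a = tcrit * se_a, ci_b = tcrit * se_b,
       r2_adj = r2_adj, p = p)
}

# Exhaustive between-class-variance search over the same candidate bin
# edges the package uses; class statistics from the raw values. Exact
# ties (edges crossing an empty gap) resolve to the centre of the tying
# edges, mirroring the convention under test.
otsu_brute_oracle <- function(values, n_bins = 256) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  sb <- rep(-Inf, n_bins - 1)
  for (k in seq_len(n_bins - 1)) {
    edge <- breaks[k + 1]
    lower <- values < edge
    n0 <- sum(lower); n1 <- sum(!lower)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(values)
    sb[k] <- w0 * (1 - w0) *
      (mean(values[lower]) - mean(values[!lower]))^2
  }
  best <- max(sb)
  mean(breaks[which(sb >= best * (1 - 1e-9)) + 1])
}

# FA from explicit eigenvalue arithmetic (no package calls).
fa_oracle <- function(lambda) {
  lambda <- pmax(lambda, 0)
  md <- mean(lambda)
  sqrt(3 / 2) * sqrt(sum((lambda - md)^2)) / sqrt(sum(lambda^2))
}

# 3D rotation matrix about an arbitrary axis (Rodrigues formula).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

default_protocol <- function() acquisition_protocol()

# Signed-data three-parameter IR fit by plain nls on the printed model;
# oracle for the magnitude fit's polarity restoration.
ir_signed_oracle <- function(y, ti, te, tr, t2) {
  f <- exp(-te / t2)
  fit <- minpack.lm::nlsLM(
    y ~ m0 * f * (1 - p * exp(-ti / t1) + exp(-tr / t1)),
    start = list(m0 = max(abs(y)) / f, p = 2, t1 = 400),
    control = minpack.lm::nls.lm.control(ptol = 1e-12, ftol = 1e-12,
                                         maxiter = 500))
  as.list(stats::coef(fit))
}
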