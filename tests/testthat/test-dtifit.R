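prot <- acquisition_protocol()
bvals_full <- c(rep(0, 3), rep(2000, 64))
dirs_full <- rbind(matrix(0, 3, 3), prot$gradient_set)

test_that("log-linear tensor fit recovers noiseless ground truth", {
  D <- diag(c(1.5e-3, 3e-4, 3e-4))
  s <- c(rep(1000, 3), simulate_dwi_signal(1000, D, 2000,
                                           prot$gradient_set))
  fit <- fit_tensor(s, bvals_full, dirs_full)
  expect_equal(fit$tensor, D, tolerance = 1e-6)
  expect_equal(fit$s0, 1000, tolerance = 1e-6)
  expect_false(fit$clamped)

  iso <- fit_tensor(c(rep(800, 3),
                      simulate_dwi_signal(800, 7e-4 * diag(3), 2000,
                                          prot$gradient_set)),
                    bvals_full, dirs_full)
  expect_equal(iso$eigenvalues, rep(7e-4, 3), tolerance = 1e-9)
})

test_that("tensor fit equals the closed-form normal-equation solution", {
  set.seed(42)
  D <- pmqmri:::tensor_from_md_fa(8e-4, 0.5, axis = c(1, 1, 2))
  s <- c(rep(500, 3), simulate_dwi_signal(500, D, 2000, prot$gradient_set))
  s <- s * exp(stats::rnorm(length(s), 0, 0.01))  # log-normal perturbation
  fit <- fit_tensor(s, bvals_full, dirs_full)

  # explicit normal equations on the same design
  g <- prot$gradient_set
  X <- cbind(1, -2000 * g[, 1]^2, -2000 * g[, 2]^2, -2000 * g[, 3]^2,
             -4000 * g[, 1] * g[, 2], -4000 * g[, 1] * g[, 3],
             -4000 * g[, 2] * g[, 3])
  X <- rbind(c(1, rep(0, 6)), X)
  y <- c(log(mean(s[1:3])), log(s[-(1:3)]))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$tensor[1, 1], beta[2], tolerance = 1e-10)
  expect_equal(fit$tensor[1, 2], beta[5], tolerance = 1e-10)
  expect_equal(fit$s0, exp(beta[1]), tolerance = 1e-10)
})

test_that("MD and FA are rotation-invariant tensor scalars", {
  D <- diag(c(1.5e-3, 3e-4, 3e-4))
  R <- rotation_matrix(c(1, 2, 3), 0.83)
  Drot <- R %*% D %*% t(R)
  s_rot <- c(rep(1000, 3), simulate_dwi_signal(1000, Drot, 2000,
                                               prot$gradient_set))
  fit <- fit_tensor(s_rot, bvals_full, dirs_full)
  expect_equal(compute_md(fit$eigenvalues), compute_md(diag(D)),
               tolerance = 1e-9)
  expect_equal(compute_fa(fit$eigenvalues), fa_oracle(diag(D)),
               tolerance = 1e-8)
})

test_that("MD and FA evaluate their defining formulas", {
  expect_equal(compute_md(diag(c(7e-4, 7e-4, 7e-4))), 7e-4)
  expect_equal(compute_md(c(1.5e-3, 3e-4, 3e-4)), 7e-4)
  expect_equal(compute_md(matrix(0, 3, 3)), 0)

  expect_equal(compute_fa(c(7e-4, 7e-4, 7e-4)), 0)
  expect_equal(compute_fa(c(1e-3, 0, 0)), 1)
  expect_true(is.na(compute_fa(matrix(0, 3, 3))))
  lam <- c(1.5e-3, 3e-4, 3e-4)
  expect_equal(compute_fa(lam), fa_oracle(lam), tolerance = 1e-12)

  # negative eigenvalues are clamped before FA
  expect_equal(compute_fa(c(1e-3, 1e-4, -1e-5)),
               fa_oracle(c(1e-3, 1e-4, 0)))
})

test_that("degenerate designs and signals are reported", {
  # all gradients collinear: cannot span the tensor
  g_bad <- matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE)
  expect_error(fit_tensor(rep(100, 11), c(0, rep(2000, 10)),
                          rbind(c(0, 0, 0), g_bad)),
               "rank-deficient")
  expect_error(fit_tensor(rep(100, 5), c(0, rep(2000, 4)),
                          matrix(0, 5, 3)), "at least 6")
  expect_error(fit_tensor(rep(100, 64), rep(2000, 64), dirs_full[4:67, ]),
               "b = 0")

  # non-positive signals are clamped and flagged
  s <- c(rep(1000, 3), simulate_dwi_signal(1000, 7e-4 * diag(3), 2000,
                                           prot$gradient_set))
  s[10] <- 0
  fit <- fit_tensor(s, bvals_full, dirs_full)
  expect_true(fit$clamped)
})

test_that("voxel-wise tensor maps match scalar fits", {
  subj <- subject_spec("s1", "post_mortem", 20, seed = 9)
  ph <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0)
  sig <- simulate_subject_signals(ph, prot, noise_sigma = 0)
  wm <- ph$labels == region_labels()[["white_matter"]]
  idx <- which(wm)[1:20]
  mask <- array(FALSE, dim = dim(wm)); mask[idx] <- TRUE
  dti <- fit_dti_map(sig$dwi, prot, mask)
  expect_equal(dti$md$values[idx], ph$maps$md[idx], tolerance = 1e-6)
  expect_equal(dti$fa$values[idx], ph$maps$fa[idx], tolerance = 1e-6)
  expect_equal(dti$n_invalid, 0L)
})
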