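prot <- acquisition_protocol()

test_that("mono-exponential fit recovers noiseless ground truth exactly", {
  s <- simulate_monoexp_signal(1000, 80, prot$se_te_list)
  f <- fit_monoexp(s, prot$se_te_list)
  expect_true(f$valid)
  expect_equal(f$s0, 1000, tolerance = 1e-8)
  expect_equal(f$t2, 80, tolerance = 1e-8)

  # T2* regime on the GRE echo list
  g <- fit_monoexp(simulate_monoexp_signal(400, 31.7, prot$gre_te_list),
                   prot$gre_te_list)
  expect_equal(g$t2, 31.7, tolerance = 1e-8)
})

test_that("degenerate decay signals are flagged invalid, not fatal", {
  f <- fit_monoexp(rep(500, 12), prot$se_te_list)
  expect_false(f$valid)
  expect_true(is.na(f$t2))
  expect_false(fit_monoexp(rep(0, 12), prot$se_te_list)$valid)
  # rising signal has no finite decay constant either
  expect_false(fit_monoexp(seq(100, 650, 50), prot$se_te_list)$valid)
  expect_error(fit_monoexp(c(1, 2), c(10, 20)), "at least 3")
})

test_that("signal scaling moves amplitudes, not time constants", {
  s <- simulate_monoexp_signal(800, 65, prot$se_te_list)
  f1 <- fit_monoexp(s, prot$se_te_list)
  f2 <- fit_monoexp(3.7 * s, prot$se_te_list)
  expect_equal(f2$s0 / f1$s0, 3.7, tolerance = 1e-8)
  expect_equal(f2$t2, f1$t2, tolerance = 1e-10)

  y <- abs(simulate_ir_se_signal(1000, 2, 700, 90, prot$ti_list,
                                 prot$ir_te, prot$ir_tr))
  g1 <- fit_t1_ir(y, prot$ti_list, prot$ir_te, prot$ir_tr, 90)
  g2 <- fit_t1_ir(2.5 * y, prot$ti_list, prot$ir_te, prot$ir_tr, 90)
  expect_equal(g2$m0 / g1$m0, 2.5, tolerance = 1e-8)
  expect_equal(g2$t1, g1$t1, tolerance = 1e-8)
  expect_equal(g2$p_factor, g1$p_factor, tolerance = 1e-8)
})

test_that("IR fit recovers noiseless ground truth from signed and magnitude data", {
  truth <- list(m0 = 1000, p = 2, t1 = 600, t2 = 80)
  y <- simulate_ir_se_signal(truth$m0, truth$p, truth$t1, truth$t2,
                             prot$ti_list, prot$ir_te, prot$ir_tr)
  signed <- fit_t1_ir(y, prot$ti_list, prot$ir_te, prot$ir_tr, truth$t2,
                      signed = TRUE)
  expect_equal(signed$t1, truth$t1, tolerance = 1e-6)
  expect_equal(signed$m0, truth$m0, tolerance = 1e-6)
  expect_equal(signed$p_factor, truth$p, tolerance = 1e-6)

  # magnitude data: polarity restoration must reach the signed solution
  mag <- fit_t1_ir(abs(y), prot$ti_list, prot$ir_te, prot$ir_tr, truth$t2)
  expect_equal(mag$t1, signed$t1, tolerance = 1e-6)
  expect_equal(mag$p_factor, signed$p_factor, tolerance = 1e-6)
  expect_equal(mag$n_restored, sum(y < 0))

  # imperfect inversion is recovered too
  y18 <- abs(simulate_ir_se_signal(1000, 1.8, 600, 80, prot$ti_list,
                                   prot$ir_te, prot$ir_tr))
  f18 <- fit_t1_ir(y18, prot$ti_list, prot$ir_te, prot$ir_tr, 80)
  expect_equal(f18$p_factor, 1.8, tolerance = 1e-6)
  expect_equal(f18$t1, 600, tolerance = 1e-6)
})

test_that("IR fit agrees with the no-TR-term model when TR >> T1", {
  # tr / t1 ~ 11.8: the exp(-TR/T1) term is ~7e-6, so a fit of data
  # generated without it must agree within 0.1%
  t1 <- 600
  y_no_tr <- 1000 * exp(-12 / 80) * (1 - 2 * exp(-prot$ti_list / t1))
  f <- fit_t1_ir(abs(y_no_tr), prot$ti_list, prot$ir_te, prot$ir_tr, 80)
  expect_equal(f$t1, t1, tolerance = 1e-3)
})

test_that("IR fit skips voxels without a valid T2", {
  y <- abs(simulate_ir_se_signal(1000, 2, 600, 80, prot$ti_list,
                                 prot$ir_te, prot$ir_tr))
  f <- fit_t1_ir(y, prot$ti_list, prot$ir_te, prot$ir_tr, NA_real_)
  expect_false(f$valid)
  expect_error(fit_t1_ir(y[1:3], prot$ti_list[1:3], 12, 7060, 80),
               "at least 4")
})

test_that("median T2 error stays within 2% at 1% Rician noise", {
  n_rep <- 1000
  s0 <- 1000; t2 <- 80
  clean <- simulate_monoexp_signal(s0, t2, prot$se_te_list)
  noisy <- add_rician_noise(
    matrix(clean, nrow = n_rep, ncol = length(clean), byrow = TRUE),
    sigma = 0.01 * s0, seed = 202)
  est <- apply(noisy, 1, function(row)
    fit_monoexp(row, prot$se_te_list)$t2)
  expect_lt(abs(stats::median(est, na.rm = TRUE) - t2) / t2, 0.02)
})

test_that("map-level driver is consistent with scalar fits and handles empty masks", {
  subj <- subject_spec("s1", "post_mortem", 15, seed = 4)
  ph <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0.02)
  sig <- simulate_subject_signals(ph, prot, noise_sigma = 0)

  empty <- array(FALSE, dim = c(16, 16, 16))
  maps <- fit_map(sig["se"], prot, empty)
  expect_true(all(is.na(maps$t2$values)))

  # single-voxel mask reproduces the scalar fit exactly
  i <- which(ph$labels == region_labels()[["white_matter"]])[5]
  single <- empty; single[i] <- TRUE
  maps1 <- fit_map(sig[c("se", "ir")], prot, single)
  flat_se <- matrix(sig$se, nrow = 16^3)
  scalar <- fit_monoexp(flat_se[i, ], prot$se_te_list)
  expect_equal(maps1$t2$values[i], scalar$t2)
  flat_ir <- matrix(sig$ir, nrow = 16^3)
  scalar_t1 <- fit_t1_ir(flat_ir[i, ], prot$ti_list, prot$ir_te,
                         prot$ir_tr, scalar$t2)
  expect_equal(maps1$t1$values[i], scalar_t1$t1)

  expect_error(fit_map(sig["ir"], prot, single), "requires the SE")
})

test_that("map-level T2 error is below 1% at 0.5% noise on a phantom", {
  subj <- subject_spec("s1", "post_mortem", 15, seed = 6)
  ph <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0)
  sig <- simulate_subject_signals(ph, prot, noise_sigma = 5, seed = 8)
  wm <- ph$labels == region_labels()[["white_matter"]]
  idx <- which(wm)[1:100]
  mask <- array(FALSE, dim = dim(wm)); mask[idx] <- TRUE
  maps <- fit_map(sig["se"], prot, mask)
  rel_err <- abs(maps$t2$values[mask] - ph$maps$t2[mask]) / ph$maps$t2[mask]
  expect_lt(stats::median(rel_err, na.rm = TRUE), 0.01)
})
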