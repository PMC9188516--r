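test_that("ground-truth lookup evaluates the tabulated lines", {
  tab <- temperature_coefficients()
  expect_equal(ground_truth_value("white_matter", "T2", 36.5, tab,
                                  "without_invivo"),
               105.4 - 0.6 * 36.5)
  # temperature 0 returns the intercept for any row
  expect_equal(ground_truth_value("thalamus", "FA", 0, tab, "with_invivo"),
               tab[tab$region == "thalamus" & tab$parameter == "FA" &
                     tab$variant == "with_invivo", "a"])
  expect_equal(ground_truth_value("putamen", "T1", 4, tab, "without_invivo"),
               526.6)
  expect_error(ground_truth_value("cerebellum", "T1", 4, tab), "no coefficient")
})

test_that("phantom carries region-wise ground truth from the linear models", {
  subj <- subject_spec("s1", "post_mortem", 5.6, seed = 2)
  ph <- generate_phantom(c(32, 32, 32), subj, within_region_cv = 0)
  lab <- region_labels()
  expect_setequal(unique(as.vector(ph$labels)), unname(lab))

  # zero within-region variation: every voxel of a region identical,
  # equal to the model value at the subject's temperature
  wm_md <- ph$maps$md[ph$labels == lab[["white_matter"]]]
  expect_equal(unique(wm_md), 1.0e-4 + 4.3e-6 * 5.6)
  put_t1 <- ph$maps$t1[ph$labels == lab[["putamen"]]]
  expect_equal(unique(put_t1), 500.6 + 6.5 * 5.6)

  # same seed reproduces the phantom bit-identically, with variation on
  ph1 <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0.05)
  ph2 <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0.05)
  expect_identical(ph1$maps, ph2$maps)

  expect_error(generate_phantom(c(8, 16, 16), subj), "at least 16")
})

test_that("partial-volume fractions are valid and mark region boundaries", {
  ph <- generate_phantom(c(16, 16, 16),
                         subject_spec("s1", "post_mortem", 12),
                         within_region_cv = 0)
  pv_all <- Reduce(`+`, ph$pv_maps)
  expect_true(all(pv_all <= 1 + 1e-6))
  expect_true(all(vapply(ph$pv_maps, function(m) all(m >= 0 & m <= 1),
                         logical(1))))
  # boundary voxels of white matter have fractional pv, interior is pure
  wm_pv <- ph$pv_maps$white_matter[ph$labels == region_labels()[["white_matter"]]]
  expect_true(any(wm_pv < 1) && any(wm_pv == 1))
})

test_that("within-region variation has the configured spread", {
  subj <- subject_spec("s1", "post_mortem", 12, seed = 31)
  ph <- generate_phantom(c(32, 32, 32), subj, within_region_cv = 0.03)
  wm <- ph$maps$t2[ph$labels == region_labels()[["white_matter"]]]
  cv_hat <- stats::sd(wm) / mean(wm)
  expect_equal(cv_hat, 0.03, tolerance = 0.2)
})

test_that("simulated signals follow the forward models voxel-wise", {
  prot <- acquisition_protocol()
  subj <- subject_spec("s1", "post_mortem", 10, seed = 5)
  ph <- generate_phantom(c(16, 16, 16), subj, within_region_cv = 0)
  sig <- simulate_subject_signals(ph, prot, noise_sigma = 0)
  i <- which(ph$labels == region_labels()[["white_matter"]])[1]
  pos <- arrayInd(i, dim(ph$labels))
  expect_equal(sig$se[pos[1], pos[2], pos[3], ],
               simulate_monoexp_signal(1000, ph$maps$t2[i], prot$se_te_list))
  expect_equal(sig$ir[pos[1], pos[2], pos[3], ],
               abs(simulate_ir_se_signal(1000, 2, ph$maps$t1[i],
                                         ph$maps$t2[i], prot$ti_list,
                                         prot$ir_te, prot$ir_tr)))
  # diffusion attenuation reproduces the voxel's tensor along x
  Dxx <- ph$maps$tensor[pos[1], pos[2], pos[3], 1]
  gx <- which.max(abs(prot$gradient_set[, 1]))
  g <- prot$gradient_set[gx, ]
  D <- matrix(NA_real_, 3, 3)
  comp <- ph$maps$tensor[pos[1], pos[2], pos[3], ]
  D[1, 1] <- comp[1]; D[2, 2] <- comp[2]; D[3, 3] <- comp[3]
  D[1, 2] <- D[2, 1] <- comp[4]; D[1, 3] <- D[3, 1] <- comp[5]
  D[2, 3] <- D[3, 2] <- comp[6]
  expect_equal(sig$dwi[pos[1], pos[2], pos[3], 3 + gx],
               simulate_dwi_signal(1000, D, 2000, g))
  expect_gt(Dxx, 0)
})

test_that("phantom tensors reproduce the prescribed MD and FA", {
  for (fa_true in c(0, 0.2, 0.77, 1)) {
    D <- pmqmri:::tensor_from_md_fa(7e-4, fa_true, axis = c(1, 2, -1))
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(mean(ev), 7e-4, tolerance = 1e-12)
    expect_equal(fa_oracle(ev), fa_true, tolerance = 1e-10)
  }
})
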