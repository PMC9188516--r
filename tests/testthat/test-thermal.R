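test_that("exact linear data are fitted exactly", {
  x <- c(5, 8, 12, 15, 20, 25, 28)
  m <- fit_linear_model(100 - 0.5 * x, x)
  expect_equal(m$intercept_a, 100, tolerance = 1e-10)
  expect_equal(m$slope_b, -0.5, tolerance = 1e-10)
  expect_equal(m$r2_adj, 1, tolerance = 1e-10)
  expect_equal(m$ci_a, 0, tolerance = 1e-7)
  expect_equal(m$ci_b, 0, tolerance = 1e-8)

  expect_error(fit_linear_model(c(1, 2, 3), rep(10, 3)), "degenerate")
  expect_error(fit_linear_model(c(1, 2), c(1, 2)), "at least 3")
})

test_that("OLS fit matches the closed-form oracle on random data", {
  set.seed(88)
  for (r in 1:25) {
    n <- sample(5:30, 1)
    x <- stats::runif(n, 5, 36)
    y <- 3 + 0.7 * x + stats::rnorm(n, 0, 2)
    m <- fit_linear_model(y, x)
    o <- ols_oracle(x, y)
    expect_equal(m$intercept_a, o$a, tolerance = 1e-10)
    expect_equal(m$slope_b, o$b, tolerance = 1e-10)
    expect_equal(m$ci_a, o$ci_a, tolerance = 1e-10)
    expect_equal(m$ci_b, o$ci_b, tolerance = 1e-10)
    expect_equal(m$r2_adj, o$r2_adj, tolerance = 1e-10)
    expect_equal(m$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("pure-noise responses typically give negative adjusted R2", {
  # under the null, R2 is right-skewed with mean 1/(n-1), which makes the
  # expectation of adjusted R2 exactly zero -- but its median is negative,
  # matching the negative printed entries for temperature-independent
  # parameters
  set.seed(31)
  r2 <- vapply(1:200, function(i) {
    x <- stats::runif(16, 5, 28)
    fit_linear_model(stats::rnorm(16), x)$r2_adj
  }, numeric(1))
  expect_lt(stats::median(r2), 0)
  expect_gt(mean(r2 < 0), 0.5)
})

test_that("predictions and Delta statistics evaluate their definitions", {
  m <- as_linear_temp_model(a = 500.6, b = 6.5, region = "putamen",
                            parameter = "T1")
  expect_equal(predict_at(m, 0), 500.6)
  expect_equal(predict_at(m, 36.5), 500.6 + 6.5 * 36.5)
  m0 <- as_linear_temp_model(a = 77, b = 0)
  expect_equal(predict_at(m0, 10), predict_at(m0, 30))

  # Delta*: percentage of the measured in vivo mean
  mm <- as_linear_temp_model(a = 610.7 - 36.5 * 0, b = 0)
  expect_equal(delta_star(mm, 610.7), 0)
  expect_equal(delta_star(mm, 600), 100 * (610.7 - 600) / 600)
  expect_equal(delta_star(as_linear_temp_model(a = 300, b = 0), 600), -50)
  expect_error(delta_star(mm, 0), "non-zero")

  # Delta**: slope 0 gives 0; unit rescaling leaves it unchanged
  expect_equal(delta_double_star(m0), 0)
  md_model <- as_linear_temp_model(a = 1.2e-4, b = 5.1e-6)
  scaled <- as_linear_temp_model(a = 1.2e-1, b = 5.1e-3)
  expect_equal(delta_double_star(md_model), delta_double_star(scaled))
})

test_that("temperature correction is exact transport along the line", {
  m <- as_linear_temp_model(a = 105.4, b = -0.6)
  expect_equal(correct_to_temperature(90, 15, 15, m), 90)
  expect_equal(correct_to_temperature(100, 10, 36.5, m),
               100 + (-0.6) * 26.5)
  # exact inverse and additive composition
  v <- 93.7
  there <- correct_to_temperature(v, 8, 36.5, m)
  expect_equal(correct_to_temperature(there, 36.5, 8, m), v)
  via <- correct_to_temperature(correct_to_temperature(v, 8, 20, m),
                                20, 36.5, m)
  expect_equal(via, there)
  expect_warning(correct_to_temperature(100, 10, 80, m), "range")
})

test_that("variant comparison reports discrepancies and CI overlap", {
  m1 <- as_linear_temp_model(a = 100, b = -0.5, ci_b = 0.2)
  cmp_same <- compare_fit_variants(m1, m1)
  expect_equal(cmp_same$difference, 0)
  expect_true(cmp_same$slope_ci_overlap)

  m2 <- as_linear_temp_model(a = 100, b = 0.5, ci_b = 0.2)
  cmp <- compare_fit_variants(m1, m2, invivo_mean = 200)
  expect_false(cmp$slope_ci_overlap)
  expect_equal(cmp$delta_star, delta_star(m2, 200))
})

test_that("cohort model driver fits both variants per cell", {
  coh <- generate_cohort(regions = c("white_matter", "putamen"),
                         parameters = c("T2", "T1"), seed = 17)
  tab <- fit_cohort_models(coh$summaries)
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_setequal(unique(tab$variant), c("without_invivo", "with_invivo"))
  wo <- tab[tab$variant == "without_invivo", ]
  expect_true(all(wo$n_subjects == 16))
  expect_true(all(is.finite(wo$delta_double_star)))
  models <- attr(tab, "models")
  expect_s3_class(models[["white_matter T2"]]$without_invivo,
                  "linear_temp_model")
  expect_s3_class(models[["white_matter T2"]]$comparison,
                  "fit_variant_comparison")
})
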