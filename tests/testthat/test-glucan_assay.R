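test_that("analytic conversion factor follows the tracer arithmetic", {
  # 0.05 uCi at 11.174 GBq/mmol diluted 7551:1, efficiency 1
  f <- derive_conversion_factor(conversion_params())
  expect_equal(f, 0.01126, tolerance = 1e-3)
  # override bypasses the derivation
  expect_equal(derive_conversion_factor(conversion_params(factor_override = 0.5)), 0.5)
  # linear in the molar ratio
  f2 <- derive_conversion_factor(conversion_params(molar_ratio = 2 * 7551))
  expect_equal(f2, 2 * f)
  expect_error(conversion_params(label_activity = -1), "positive")
  expect_error(conversion_params(counting_efficiency = 1.5), "0, 1")
})

test_that("calibration recovers the slope through the origin", {
  f <- calibrate_conversion_factor(c(5670, 12900, 10100, 22200),
                                   c(50.0, 113, 89.0, 195))
  expect_gte(f, 0.0087)
  expect_lte(f, 0.0089)
  expect_equal(calibrate_conversion_factor(100, 1), 0.01)
  expect_equal(calibrate_conversion_factor(c(10, 20), c(0, 0)), 0)
  expect_error(calibrate_conversion_factor(numeric(), numeric()), "at least one")
  # scale equivariance: scaling cpm and nmol together leaves the factor alone
  set.seed(11)
  cpm <- runif(6, 100, 1e4); nmol <- cpm * 0.0088 * (1 + rnorm(6, sd = 0.01))
  expect_equal(calibrate_conversion_factor(cpm * 3.7, nmol * 3.7),
               calibrate_conversion_factor(cpm, nmol))
})

test_that("cpm to nmol conversion is linear and additive", {
  f <- calibrate_conversion_factor(c(5670, 12900, 10100, 22200),
                                   c(50.0, 113, 89.0, 195))
  expect_equal(cpm_to_nmol(0, f), 0)
  expect_equal(cpm_to_nmol(5670, f), 50, tolerance = 0.01)
  expect_equal(cpm_to_nmol(100 + 250, f), cpm_to_nmol(100, f) + cpm_to_nmol(250, f))
  expect_error(cpm_to_nmol(-1, f), "non-negative")
})

test_that("method ratios reproduce the printed comparison table", {
  expect_equal(method_ratio(10100, 5670), 1.78)
  expect_equal(method_ratio(22200, 12900), 1.72)
  expect_equal(method_ratio(89.0, 50.0), 1.78)
  expect_equal(method_ratio(195, 113), 1.73)
  expect_equal(method_ratio(7, 7), 1.00)
  expect_error(method_ratio(1, 0), "positive")
})

test_that("digestion-fraction accounting splits callose and cellulose", {
  r <- fraction_accounting(100, 90, 10)
  expect_equal(r$crystalline_share, 0.10)
  expect_equal(r$b14_total, 100)
  expect_equal(r$callose, 100)
  r <- fraction_accounting(0, 80, 20)
  expect_equal(r$crystalline_share, 0.20)
  expect_true(is.na(r$b14_to_b13_ratio))
  expect_error(fraction_accounting(50, 0, 0), "undefined")
  expect_error(fraction_accounting(-1, 10, 1), "non-negative")
})

test_that("fold change and the pooled t-test behave classically", {
  expect_equal(fold_change(360, 100), 3.6)
  expect_equal(fold_change(55, 55), 1.0)
  expect_error(fold_change(1, 0), "positive")
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)
  ident <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  swapped <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p_value, r$p_value)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("the assay summary reproduces the printed ratios and factor spread", {
  s <- summarize_assay(load_fixture("table1"))
  se <- s[s$method == "sedimentation_velocity", ]
  expect_equal(se$se_su_cpm[se$glucan == "b14"], 1.78)
  expect_equal(se$se_su_cpm[se$glucan == "b13"], 1.72)
  expect_equal(se$se_su_nmol[se$glucan == "b14"], 1.78)
  expect_equal(se$se_su_nmol[se$glucan == "b13"], 1.73)
  expect_lte(glance(s)$implied_factor_spread, 0.015)
  # replicate-level input: per-group means and pooled t-tests downstream
  sim <- simulate_assay(c(b14 = 89, b13 = 195), factor = 0.0088,
                        noise_cv = 0, n_replicates = 3, seed = 1)
  tbl <- tibble::tibble(method = "sedimentation_velocity", glucan = sim$sample_id,
                        cpm_per_mg = sim$cpm_per_mg)
  su <- tibble::tibble(method = "sucrose_density", glucan = sim$sample_id,
                       cpm_per_mg = sim$cpm_per_mg / 2)
  s2 <- summarize_assay(dplyr::bind_rows(tbl, su), factor = 0.0088)
  expect_equal(s2$se_su_cpm[s2$method == "sedimentation_velocity"], c(2, 2))
})
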