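test_that("objective is zero at the truth on noiseless data", {
  g <- noiseless_patient()
  cfg <- fit_config(rtol_polish = 1e-8)
  expect_lt(objective(g$truth, g$dataset, cfg), 1e-10)
})

test_that("the noiseless optimum is a local minimum along every axis", {
  g <- noiseless_patient()
  cfg <- fit_config()
  base <- objective(g$truth, g$dataset, cfg)
  for (nm in free_param_names()) {
    p <- g$truth
    p[[nm]] <- p[[nm]] * 1.1
    if (nm == "f_abs") p[[nm]] <- min(p[[nm]], 1)
    expect_gt(objective(p, g$dataset, cfg), base + 1e-6)
  }
})

test_that("a fully masked series contributes nothing to the objective", {
  g <- noiseless_patient()
  cfg <- fit_config()
  p <- g$truth
  p$P_B1 <- p$P_B1 * 1.3   # makes V1B residuals non-trivial
  d1 <- g$dataset
  d1$concentrations$V1B$values <- rep(NA_real_, 16)
  d2 <- g$dataset
  d2$concentrations$V1B$values <- rep(999, 16)
  d2$concentrations$V1B$values[] <- NA_real_
  expect_equal(objective(p, d1, cfg), objective(p, d2, cfg))
  expect_lt(objective(p, d1, cfg), objective(p, g$dataset, cfg))
})

test_that("precursor fitting recovers known coefficients", {
  g <- noiseless_patient()
  ds <- g$dataset
  tm <- ds$schedule$times_min
  # single-exponential truth, noiseless: recovery to 1e-4 relative
  ds$enrichments$Plasma_leu <- enrichment_series(
    "Plasma_leu", 8 * exp(-0.01 * tm))
  fp <- fit_precursor(ds, n_terms = 1)
  expect_equal(fp$leu$A, 8, tolerance = 1e-4)
  expect_equal(fp$leu$lambda, 0.01, tolerance = 1e-4)
  # all-zero MPE -> zero amplitudes
  ds$enrichments$Plasma_gly <- enrichment_series("Plasma_gly", rep(0, 16))
  expect_equal(fit_precursor(ds, n_terms = 2)$gly$A, c(0, 0))
  # nested models: 3 terms fit 3-term data at least as well as 2
  y3 <- 4 * exp(-0.08 * tm) + 3 * exp(-0.012 * tm) + 1.5 * exp(-0.0012 * tm)
  ds$enrichments$Plasma_leu <- enrichment_series("Plasma_leu", y3)
  f2 <- fit_precursor(ds, n_terms = 2)$leu
  f3 <- fit_precursor(ds, n_terms = 3)$leu
  expect_lt(f3$resid_norm, f2$resid_norm)
  # non-decaying data warn and fall back to the monotone family
  ds$enrichments$Plasma_leu <- enrichment_series(
    "Plasma_leu", seq(1, 4, length.out = 16))
  expect_warning(fit_precursor(ds, n_terms = 2), "decay")
})

test_that("the default 2-vs-3 term rule keeps the extra term only when it
           clearly helps", {
  g <- noiseless_patient()
  fp <- fit_precursor(g$dataset)
  expect_length(fp$leu$A, 2)  # truth is 2-exponential
  expect_lt(fp$leu$resid_norm, 1e-4)
})

test_that("fit is reproducible and improves with more starts", {
  g <- noiseless_patient()
  cfgA <- cheap_fit_config(n_starts = 3, seed = 5)
  f1 <- fit_patient(g$dataset, cfgA)
  f2 <- fit_patient(g$dataset, cfgA)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$objective, f2$objective)
  f6 <- fit_patient(g$dataset, cheap_fit_config(n_starts = 6, seed = 5))
  expect_lte(f6$objective, f1$objective * (1 + 1e-8))
})

test_that("a patient with no insulin effect is flagged as such", {
  rg <- default_parameter_ranges()
  rg$pre$ISI <- c(0, 0)
  cfg <- cohort_config(n_patients = 1, seed = 17,
                       noise_cv = c(concentration = 0, enrichment = 0),
                       parameter_ranges = rg)
  g <- generate_patient("pre", cfg, 1)
  expect_equal(g$truth$ISI, 0)
  fit <- fit_patient(g$dataset, cheap_fit_config(n_starts = 8, seed = 3))
  expect_false(fit$insulin_effect_detected)
  expect_lt(fit$params$ISI, 0.05)
})

test_that("fit results carry diagnostics within their contracts", {
  g <- noiseless_patient()
  fit <- cached("cheap_fit_pre",
                fit_patient(g$dataset, cheap_fit_config(n_starts = 6)))
  expect_gte(fit$objective, 0)
  expect_length(fit$start_objectives, 6)
  expect_gte(fit$n_within_1pct, 1)
  for (nm in free_param_names()) {
    b <- default_fit_bounds()[[nm]]
    expect_gte(fit$params[[nm]], b[1] - 1e-12)
    expect_lte(fit$params[[nm]], b[2] + 1e-12)
  }
  expect_true(all(!is.na(unlist(fit$residuals))))
  # curvature-based uncertainty is finite and positive where defined
  un <- fit_uncertainty(fit, g$dataset, cheap_fit_config(n_starts = 6))
  expect_identical(un$parameter, free_param_names())
  expect_true(all(is.na(un$se_approx) | un$se_approx >= 0))
})
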