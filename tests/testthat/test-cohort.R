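test_that("parameter sampling is deterministic and honours ranges", {
  cfg <- cohort_config(n_patients = 2, seed = 9)
  set.seed(1); a <- sample_parameters("pre", cfg)
  set.seed(1); b <- sample_parameters("pre", cfg)
  expect_identical(unclass(a), unclass(b))
  # degenerate ranges are point masses
  rg <- default_parameter_ranges()
  for (nm in names(rg$pre)) rg$pre[[nm]] <- c(rg$pre[[nm]][1], rg$pre[[nm]][1])
  cfg2 <- cohort_config(parameter_ranges = rg)
  set.seed(2); d <- sample_parameters("pre", cfg2)
  expect_equal(d$P_B1, rg$pre$P_B1[1])
  expect_equal(d$ISI, rg$pre$ISI[1])
  # draws stay inside their intervals
  set.seed(3)
  for (i in 1:50) {
    s <- sample_parameters("post", cfg)
    for (nm in names(rg$post)) {
      expect_gte(s[[nm]], cohort_config()$parameter_ranges$post[[nm]][1])
      expect_lte(s[[nm]], cohort_config()$parameter_ranges$post[[nm]][2])
    }
  }
  expect_error(cohort_config(parameter_ranges = list(
    pre = list(P_B1 = c(5, 1)), post = list())),
    class = "vldlkin_config_error")
})

test_that("the configured ISI shift moves the cohort mean", {
  cfg <- cohort_config()
  set.seed(4)
  pre <- replicate(1000, sample_parameters("pre", cfg)$ISI)
  post <- replicate(1000, sample_parameters("post", cfg)$ISI)
  expect_gt(mean(post), mean(pre))
})

test_that("noiseless generation equals the model observables exactly", {
  g <- noiseless_patient()
  ds <- g$dataset
  f <- build_insulin_forcing(ds$concentrations$Insulin, ds$schedule)
  sim <- simulate_model(g$truth, ds$schedule, ds$meal, ds$tracer, f,
                        ds$body_weight, dense_dt_min = 1440)
  for (sp in c("V1B", "V2B", "V1TG", "V2TG", "CMTG", "PlasmaTG"))
    expect_equal(ds$concentrations[[sp]]$values, sim$concentrations[[sp]],
                 tolerance = 1e-10)
  for (pool in c("V1B_leu", "V2B_leu", "V1TG_gly", "V2TG_gly"))
    expect_equal(ds$enrichments[[pool]]$values, sim$enrichments[[pool]],
                 tolerance = 1e-10)
  # plasma precursor series equal the forcing curves
  expect_equal(ds$enrichments$Plasma_leu$values,
               precursor_enrichment(ds$schedule$times_min,
                                    g$truth$precursor_leu))
  expect_identical(ds$schedule$times_min, as.numeric(STUDY_TIMES_MIN))
})

test_that("multiplicative noise has the configured CV", {
  set.seed(7)
  f <- vldlkin:::noise_factor(200, 0.05)
  expect_lt(abs(sd(f) / mean(f) - 0.05) / 0.05, 0.15)
  expect_identical(vldlkin:::noise_factor(5, 0), rep(1, 5))
})

test_that("cohort generation is reproducible and seed-sensitive", {
  cfg <- cohort_config(n_patients = 2, seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(
    jsonlite::toJSON(c1$manifest, digits = NA),
    jsonlite::toJSON(c2$manifest, digits = NA))
  expect_identical(c1$datasets$S001_pre$concentrations$V1TG$values,
                   c2$datasets$S001_pre$concentrations$V1TG$values)
  c3 <- generate_cohort(cohort_config(n_patients = 2, seed = 22))
  expect_false(identical(c1$datasets$S001_pre$concentrations$V1TG$values,
                         c3$datasets$S001_pre$concentrations$V1TG$values))
  # pairing: n patients, 2 conditions each
  expect_length(c1$datasets, 4)
  expect_setequal(c1$manifest$condition[c1$manifest$patient_id == "S001"],
                  c("pre", "post"))
})

test_that("generated cohorts reproduce the configured contrasts (n = 100)", {
  cfg <- cohort_config(n_patients = 100, seed = 31, with_clamp = FALSE)
  man <- generate_cohort(cfg)$manifest
  pre <- man[man$condition == "pre", ]
  post <- man[man$condition == "post", ]
  for (nm in names(cfg$contrasts)) {
    delta <- mean(post[[nm]]) - mean(pre[[nm]])
    if (cfg$contrasts[[nm]] == "increase") expect_gt(delta, 0)
    else expect_lt(delta, 0)
  }
})
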