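grid_sched <- function(times_min) sampling_schedule(times_min = times_min)

test_that("postprandial AUC is the masked trapezoid over 2-10 h", {
  sched <- sampling_schedule()
  const <- concentration_series("V1TG", rep(10, 16))
  expect_equal(compute_auc(const, sched), 80)   # rectangle
  # linear ramp 0 -> 10 over the 8-h window
  th <- sched$times_min / 60
  ramp <- pmax(0, pmin(10, (th - 2) / 8 * 10))
  expect_equal(compute_auc(concentration_series("V1TG", ramp), sched), 40)
  # hand-summed oracle on a cubic sampled at the study grid
  y <- 2 + 0.5 * th - 0.03 * th^2 + 0.001 * th^3
  keep <- th >= 2 & th <= 10
  x <- th[keep]; v <- y[keep]
  hand <- 0
  for (i in seq_len(length(x) - 1))
    hand <- hand + (x[i + 1] - x[i]) * (v[i] + v[i + 1]) / 2
  expect_equal(compute_auc(concentration_series("V1TG", y), sched), hand,
               tolerance = 1e-12)
  # masking excludes samples; < 2 usable samples is undefined, not zero
  masked <- rep(NA_real_, 16); masked[10] <- 5
  expect_true(is.na(compute_auc(concentration_series("V1TG", masked), sched)))
})

test_that("AUC is additive over windows and collinear-point invariant", {
  sched <- sampling_schedule()
  y <- abs(sin(sched$times_min / 200)) * 50
  s <- concentration_series("V1TG", y)
  expect_equal(compute_auc(s, sched, c(2, 6)) + compute_auc(s, sched, c(6, 10)),
               compute_auc(s, sched, c(2, 10)))
  # insert a collinear sample between 240 and 300 min
  t2 <- sort(c(sched$times_min, 270))
  y2 <- approx(sched$times_min, y, xout = t2)$y
  expect_equal(compute_auc(concentration_series("V1TG", y2), grid_sched(t2)),
               compute_auc(s, sched), tolerance = 1e-12)
})

test_that("peak time picks the earliest argmax on the observed grid", {
  sched <- sampling_schedule()
  y <- rep(1, 16); y[11] <- 9            # 240 min
  expect_equal(peak_time(concentration_series("V1TG", y), sched), 4)
  y[12] <- 9                             # tie at 240 and 300 -> earliest
  expect_equal(peak_time(concentration_series("V1TG", y), sched), 4)
  inc <- seq_len(16)                     # monotone -> window end (10 h)
  expect_equal(peak_time(concentration_series("V1TG", inc), sched), 10)
  expect_true(is.na(peak_time(concentration_series("V1TG", rep(NA_real_, 16)),
                              sched)))
})

test_that("TG:apoB ratio and percent change are guarded divisions", {
  expect_equal(tg_apob_ratio(5, 5), 1)
  expect_equal(tg_apob_ratio(62.2, 2), 31.1)
  expect_true(is.na(tg_apob_ratio(10, 0)))
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 17.2), 72)
  expect_equal(percent_change(10, 5), -50)
  expect_true(is.na(percent_change(0, 5)))
})

test_that("derived kinetic summaries honour the identities", {
  g <- noiseless_patient()
  # FCR identity and direct-secretion fraction
  p <- model_parameters(P_B1 = 13.6, P_B2d = 6.4, k_FTR_B = 3, k_FDC_B1 = 2)
  ks <- true_kinetics(p, g$dataset)
  expect_equal(ks$FCR_B1, 5)
  expect_equal(ks$pct_direct_B2, 32)
  # total = direct + transfer inflow: M_V1B = 4.5/3 = 1.5, k_FTR_B = 2
  p2 <- model_parameters(P_B1 = 4.5, P_B2d = 4, k_FTR_B = 2, k_FDC_B1 = 1)
  ks2 <- true_kinetics(p2, g$dataset)
  expect_equal(ks2$P_B2_total, 7)
  # invariants over random parameter draws
  set.seed(8)
  cfg <- cohort_config()
  for (i in 1:20) {
    ps <- sample_parameters(sample(c("pre", "post"), 1), cfg)
    k <- true_kinetics(ps, g$dataset)
    expect_equal(k$FCR_B1, ps$k_FTR_B + ps$k_FDC_B1)
    expect_equal(k$FCR_T1, ps$k_FTR_T + ps$k_FDC_T1)
    expect_gte(k$P_B2_total, k$P_B2d)
    expect_gte(k$P_T2_total, k$P_T2d)
    expect_true(k$pct_direct_B2 >= 0 && k$pct_direct_B2 <= 100)
    expect_true(k$pct_direct_T2 >= 0 && k$pct_direct_T2 <= 100)
  }
})

test_that("derive_kinetics consumes a fit and matches its parameters", {
  g <- noiseless_patient()
  fit <- cached("cheap_fit_pre",
                fit_patient(g$dataset, cheap_fit_config(n_starts = 6)))
  ks <- derive_kinetics(fit, g$dataset)
  expect_s3_class(ks, "kinetic_summary")
  expect_equal(ks$P_B1, fit$params$P_B1)
  expect_equal(ks$FCR_B1, fit$params$k_FTR_B + fit$params$k_FDC_B1)
  expect_equal(ks$homa_ir,
               homa_ir(g$dataset$fasting_glucose, g$dataset$fasting_insulin))
  # the summary's AUCs come from the observed series
  expect_equal(ks$auc_V1TG,
               compute_auc(g$dataset$concentrations$V1TG,
                           g$dataset$schedule))
})
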