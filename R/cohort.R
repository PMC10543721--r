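## Synthetic cohort generator: virtual paired pre/post patients with known
## ground-truth parameters, emulating the mixed-meal tracer protocol (tracer
## bolus at 0, meal at 120 min over 10 min pre / 30 min post, the fixed
## 5..1440 min grid) with proportional measurement noise.

#' Condition-specific ground-truth parameter sampling ranges
#'
#' Ranges are centred on cohort-scale values and shifted between conditions
#' to reproduce the directional surgery effects: lower VLDL1 apoB/TG and
#' VLDL2 TG direct production, higher TG catabolic and transfer rates,
#' higher CM TG clearance, lower intestinal absorption, higher lipolysis
#' ISI after surgery.
#' @return list with elements `pre` and `post`, each a named list of
#'   `c(min, max)` intervals.
#' @export
default_parameter_ranges <- function() {
  list(
    pre = list(
      P_B1 = c(10, 20), P_B2d = c(4, 8), P_T1 = c(450, 850),
      P_T2d = c(70, 150), k_FTR_B = c(2, 4), k_FDC_B1 = c(1, 2.5),
      k_FCR_B2 = c(2, 4), k_FTR_T = c(6, 14), k_FDC_T1 = c(10, 20),
      k_FCR_T2 = c(6, 16), k_CM = c(18, 38), f_abs = c(0.75, 0.95),
      ISI = c(0, 0.4)),
    post = list(
      P_B1 = c(6, 12), P_B2d = c(4, 8), P_T1 = c(220, 450),
      P_T2d = c(50, 110), k_FTR_B = c(2.5, 5), k_FDC_B1 = c(1, 2.5),
      k_FCR_B2 = c(2.5, 5), k_FTR_T = c(9, 18), k_FDC_T1 = c(10, 20),
      k_FCR_T2 = c(10, 24), k_CM = c(32, 64), f_abs = c(0.5, 0.75),
      ISI = c(0.1, 0.7)))
}

# directional pre -> post contrasts built into the default ranges
default_contrasts <- function() {
  c(P_B1 = "decrease", P_T1 = "decrease", P_T2d = "decrease",
    k_FTR_B = "increase", k_FCR_B2 = "increase", k_FTR_T = "increase",
    k_FCR_T2 = "increase", k_CM = "increase", f_abs = "decrease",
    ISI = "increase")
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of pre/post pairs.
#' @param seed integer RNG seed; every draw derives from it.
#' @param noise_cv proportional (lognormal) noise CV per observable class:
#'   named vector with `concentration` and `enrichment`.
#' @param parameter_ranges see [default_parameter_ranges()].
#' @param insulin_template per-condition basal range (mU/L), postprandial
#'   peak as multiple of basal, and time-to-peak range (min after meal
#'   start); the excursion returns to basal by about 4 h.
#' @param with_clamp also generate a two-step clamp record per dataset.
#' @export
cohort_config <- function(n_patients = 24, seed = 1,
                          noise_cv = c(concentration = 0.05,
                                       enrichment = 0.08),
                          parameter_ranges = default_parameter_ranges(),
                          insulin_template = list(
                            basal = list(pre = c(10, 20), post = c(4, 9)),
                            peak_mult = list(pre = c(3, 5), post = c(5, 8)),
                            t_peak_min = c(30, 60)),
                          with_clamp = TRUE) {
  if (n_patients < 1) vldl_error("n_patients must be >= 1",
                                 "vldlkin_config_error")
  if (any(noise_cv < 0)) vldl_error("noise_cv must be >= 0",
                                    "vldlkin_config_error")
  for (cond in c("pre", "post"))
    for (nm in names(parameter_ranges[[cond]])) {
      rg <- parameter_ranges[[cond]][[nm]]
      if (length(rg) != 2 || rg[2] < rg[1])
        vldl_error(sprintf("empty range for %s (%s)", nm, cond),
                   "vldlkin_config_error")
    }
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), noise_cv = noise_cv,
                 parameter_ranges = parameter_ranges,
                 insulin_template = insulin_template,
                 contrasts = default_contrasts(),
                 with_clamp = isTRUE(with_clamp)),
            class = "cohort_config")
}

# log-uniform draw on [lo, hi]; plain uniform when lo == 0 (ISI) or lo == hi
draw_range <- function(rg, log_scale = TRUE) {
  if (rg[1] == rg[2]) return(rg[1])
  if (!log_scale || rg[1] <= 0) return(runif(1, rg[1], rg[2]))
  exp(runif(1, log(rg[1]), log(rg[2])))
}

#' Sample ground-truth parameters for one condition
#'
#' Log-uniform draws within the condition's configured ranges (uniform for
#' ISI, whose presurgery range includes 0). `latent` optionally correlates
#' the production draws with a patient-level insulin-resistance quantile so
#' that production and HOMA-IR co-vary as in the clinical cohort.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param condition `"pre"` or `"post"`.
#' @param config a [cohort_config()].
#' @param latent optional insulin-resistance quantile in \[0, 1\].
#' @return a [model_parameters()] object.
#' @export
sample_parameters <- function(condition, config, latent = NULL) {
  rgs <- config$parameter_ranges[[match.arg(condition, c("pre", "post"))]]
  draws <- list()
  for (nm in names(rgs)) {
    rg <- rgs[[nm]]
    if (!is.null(latent) && nm %in% c("P_B1", "P_T1") && rg[1] < rg[2]) {
      # blend the shared insulin-resistance quantile with an independent one
      q <- 0.6 * latent + 0.4 * runif(1)
      draws[[nm]] <- if (rg[1] > 0) exp(log(rg[1]) + q * log(rg[2] / rg[1]))
        else rg[1] + q * (rg[2] - rg[1])
    } else {
      draws[[nm]] <- draw_range(rg, log_scale = nm != "ISI")
    }
  }
  do.call(model_parameters, draws)
}

# postprandial insulin excursion template: gamma-shaped bump over basal
insulin_curve <- function(t_min, meal_time_min, I_b, peak_mult, t_peak_min,
                          shape = 2) {
  s <- pmax(0, t_min - meal_time_min)
  g <- (s / t_peak_min)^shape * exp(shape * (1 - s / t_peak_min))
  I_b * (1 + (peak_mult - 1) * g)
}

# mean-one lognormal multiplicative noise with coefficient of variation cv
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sig <- sqrt(log(1 + cv^2))
  exp(rnorm(n, 0, sig) - sig^2 / 2)
}

# clamp record engineered so that the tissue indices recovered by
# clamp_summary() equal the targets (plateaus are steady in the last 30 min)
make_clamp_record <- function(basal_insulin, targets) {
  F <- 0.11
  tgrid <- function(t0) seq(t0 - 50, t0, by = 10)
  tm <- c(tgrid(120), tgrid(240), tgrid(360))
  step <- rep(c("basal", "step1", "step2"), each = 6)
  ra_glu0 <- targets$basal_EGP
  ra_gly0 <- targets$basal_lipolysis
  egp1 <- ra_glu0 * (1 - targets$EGP_suppression / 100)
  gir1 <- 0.4 * ra_glu0
  ra1 <- egp1 + gir1
  rd2 <- ra_glu0 * (1 + targets$Rd_stimulation / 100)
  egp2 <- 0.1 * ra_glu0
  gir2 <- rd2 - egp2
  gly1 <- ra_gly0 * (1 - targets$lipolysis_suppression / 100)
  glu_ttr <- rep(F / c(ra_glu0, ra1, rd2), each = 6)
  gly_ttr <- rep(F / c(ra_gly0, gly1, 0.9 * gly1), each = 6)
  clamp_record(
    time_min = tm, step = step,
    glucose_conc = rep(5, 18), glucose_ttr = glu_ttr,
    glycerol_conc = rep(c(80, 45, 35), each = 6), glycerol_ttr = gly_ttr,
    exo_glucose_infusion = rep(c(0, gir1, gir2), each = 6),
    basal_insulin = basal_insulin,
    step1_insulin = basal_insulin + 40,
    step2_insulin = basal_insulin + 130)
}

#' Generate one virtual patient-condition dataset
#'
#' Simulates the forward model at the sampled ground-truth parameters on the
#' exact study grid, then adds multiplicative lognormal noise per sample
#' (configured CV per observable class). The insulin series comes from the
#' exogenous template, never from the lipoprotein model, and is shared
#' un-noised between truth and observation; MPE values are clipped to
#' \[0, 100\] after noising.
#'
#' @param condition `"pre"` or `"post"`.
#' @param config a [cohort_config()].
#' @param patient_index integer used to derive the patient's RNG streams.
#' @param shared list with `height` (m) and `body_weight` (kg) for this
#'   patient-condition.
#' @return `list(dataset = patient_dataset, truth = model_parameters,
#'   clamp_targets = list)`.
#' @export
generate_patient <- function(condition, config, patient_index = 1,
                             shared = NULL) {
  condition <- match.arg(condition, c("pre", "post"))
  base_seed <- config$seed + 1009L * patient_index +
    ifelse(condition == "post", 499L, 0L)

  # --- parameter stream ---
  set.seed(base_seed)
  latent <- runif(1)
  truth <- sample_parameters(condition, config, latent = latent)
  tpl <- config$insulin_template
  I_b <- draw_range(tpl$basal[[condition]], log_scale = FALSE)
  peak_mult <- draw_range(tpl$peak_mult[[condition]], log_scale = FALSE)
  t_peak <- draw_range(tpl$t_peak_min, log_scale = FALSE)
  if (is.null(shared)) {
    height <- runif(1, 1.60, 1.90)
    bw <- runif(1, 105, 145)
    if (condition == "post") bw <- bw * runif(1, 0.65, 0.78)
    shared <- list(height = height, body_weight = bw)
  }
  fasting_glucose <- if (condition == "pre") runif(1, 4.8, 6.2) else
    runif(1, 4.4, 5.4)
  # insulin resistance raises fasting insulin with the shared latent
  fasting_insulin <- I_b
  clamp_targets <- list(
    basal_EGP = runif(1, 8, 13),
    basal_lipolysis = runif(1, 2, 3.5),
    EGP_suppression = min(95, max(5, 30 + 70 * truth$ISI + rnorm(1, 0, 5))),
    Rd_stimulation = min(400, max(10, 40 + 250 * truth$ISI + rnorm(1, 0, 15))),
    lipolysis_suppression = min(95, max(5, 25 + 80 * truth$ISI +
                                          rnorm(1, 0, 5))))

  # --- deterministic truth simulation ---
  sched <- sampling_schedule(
    meal_duration_min = if (condition == "pre") 10 else 30)
  tm <- sched$times_min
  ins_vals <- insulin_curve(tm, sched$meal_time_min, I_b, peak_mult, t_peak)
  ins_series <- concentration_series("Insulin", ins_vals)
  forcing <- build_insulin_forcing(ins_series, sched)
  meal <- meal_spec(ingestion_duration_min = sched$meal_duration_min)
  tracer <- tracer_protocol()
  sim <- simulate_model(truth, sched, meal, tracer, forcing,
                        shared$body_weight, dense_dt_min = 1440)

  # --- noise stream ---
  set.seed(base_seed + 500000L)
  cvc <- config$noise_cv[["concentration"]]
  cve <- config$noise_cv[["enrichment"]]
  noisy_conc <- function(v) v * noise_factor(length(v), cvc)
  noisy_mpe <- function(v) pmin(100, pmax(0, v * noise_factor(length(v), cve)))

  glucose_vals <- noisy_conc(
    fasting_glucose + 1.5 * exp(-((tm - sched$meal_time_min - 40) / 60)^2) *
      (tm > sched$meal_time_min))
  conc <- list(
    concentration_series("V1B", noisy_conc(sim$concentrations$V1B)),
    concentration_series("V2B", noisy_conc(sim$concentrations$V2B)),
    concentration_series("V1TG", noisy_conc(sim$concentrations$V1TG)),
    concentration_series("V2TG", noisy_conc(sim$concentrations$V2TG)),
    concentration_series("CMTG", noisy_conc(sim$concentrations$CMTG)),
    concentration_series("PlasmaTG", noisy_conc(sim$concentrations$PlasmaTG)),
    ins_series,
    concentration_series("Glucose", glucose_vals))
  enr <- list(
    enrichment_series("V1B_leu", noisy_mpe(sim$enrichments$V1B_leu)),
    enrichment_series("V2B_leu", noisy_mpe(sim$enrichments$V2B_leu)),
    enrichment_series("V1TG_gly", noisy_mpe(sim$enrichments$V1TG_gly)),
    enrichment_series("V2TG_gly", noisy_mpe(sim$enrichments$V2TG_gly)),
    enrichment_series("Plasma_leu",
                      noisy_mpe(precursor_enrichment(tm, truth$precursor_leu))),
    enrichment_series("Plasma_gly",
                      noisy_mpe(precursor_enrichment(tm, truth$precursor_gly))))

  clamp <- if (config$with_clamp)
    make_clamp_record(fasting_insulin, clamp_targets)

  ds <- patient_dataset(
    patient_id = sprintf("S%03d", patient_index), condition = condition,
    body_weight = shared$body_weight, height = shared$height,
    schedule = sched, concentrations = conc, enrichments = enr,
    meal = meal, tracer = tracer, fasting_glucose = fasting_glucose,
    fasting_insulin = fasting_insulin, clamp = clamp)
  list(dataset = ds, truth = truth, clamp_targets = clamp_targets)
}

#' Generate a paired pre/post cohort
#'
#' Fully reproducible from `config$seed`: each patient-condition has its own
#' derived RNG streams (one for parameter draws, one for noise), so adding
#' observables or patients does not perturb other draws.
#'
#' @param config a [cohort_config()].
#' @return list with `datasets` (length `2 n`, pre and post interleaved),
#'   `truth` (named list of [model_parameters()] keyed `id_condition`) and
#'   `manifest` (data.frame of ids, conditions and true parameter values).
#' @export
generate_cohort <- function(config) {
  datasets <- list()
  truth <- list()
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(config$seed + 7919L * i)
    height <- runif(1, 1.60, 1.90)
    bw_pre <- runif(1, 105, 145)
    bw_post <- bw_pre * runif(1, 0.65, 0.78)
    for (cond in c("pre", "post")) {
      g <- generate_patient(cond, config, patient_index = i,
                            shared = list(height = height,
                                          body_weight = if (cond == "pre")
                                            bw_pre else bw_post))
      key <- sprintf("%s_%s", g$dataset$patient_id, cond)
      datasets[[key]] <- g$dataset
      truth[[key]] <- g$truth
      pr <- g$truth[c("P_B1", "P_B2d", "P_T1", "P_T2d", "k_FTR_B",
                      "k_FDC_B1", "k_FCR_B2", "k_FTR_T", "k_FDC_T1",
                      "k_FCR_T2", "k_CM", "f_abs", "ISI")]
      rows[[key]] <- data.frame(patient_id = g$dataset$patient_id,
                                condition = cond, as.data.frame(pr))
    }
  }
  list(datasets = datasets, truth = truth,
       manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
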