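#' @useDynLib vldlkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor lm median optim pt qt quantile rlnorm
#'   rnorm runif sd setNames t.test var
#' @importFrom utils read.csv write.csv modifyList head
"_PACKAGE"

## ---- vocabulary -----------------------------------------------------------

#' Species and enrichment-pool vocabularies
#'
#' Fixed names used throughout the package for observed time series.
#' Concentration species: VLDL1/VLDL2 apoB and TG, chylomicron TG, total
#' plasma TG (all mg/dL), insulin (mU/L) and glucose (mmol/L). Enrichment
#' pools are molar percent excess (MPE, %) of leucine in VLDL apoB and of
#' glycerol in VLDL TG, plus the plasma precursor curves.
#' @name vocabulary
#' @keywords internal
NULL

CONC_SPECIES <- c("V1B", "V2B", "V1TG", "V2TG", "CMTG", "PlasmaTG",
                  "Insulin", "Glucose")
ENRICH_POOLS <- c("V1B_leu", "V2B_leu", "V1TG_gly", "V2TG_gly",
                  "Plasma_leu", "Plasma_gly")

#' Reference mixed-meal sampling grid (minutes post tracer)
#' @export
STUDY_TIMES_MIN <- c(5, 15, 30, 45, 60, 75, 90, 120, 150, 180,
                     240, 300, 360, 480, 600, 1440)

vldl_error <- function(msg, class) {
  stop(structure(class = c(class, "vldlkin_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## ---- sampling schedule ----------------------------------------------------

#' Sampling schedule of a mixed-meal tracer study
#'
#' @param times_min strictly increasing sample times, minutes post tracer.
#' @param meal_time_min meal start, minutes post tracer (protocol: 120).
#' @param meal_duration_min meal ingestion duration, minutes (10 before
#'   surgery, 30 at follow-up).
#' @param study_end_min end of the observation window; defaults to the last
#'   sample.
#' @return object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(times_min = STUDY_TIMES_MIN,
                              meal_time_min = 120,
                              meal_duration_min = 10,
                              study_end_min = max(times_min)) {
  times_min <- as.numeric(times_min)
  if (length(times_min) < 2 || any(diff(times_min) <= 0))
    vldl_error("sample times must be strictly increasing",
               "vldlkin_validation_error")
  if (meal_duration_min <= 0)
    vldl_error("meal_duration_min must be > 0", "vldlkin_validation_error")
  if (meal_time_min < min(times_min) || meal_time_min > max(times_min))
    vldl_error("meal_time_min must lie within the sampling grid",
               "vldlkin_validation_error")
  structure(list(times_min = times_min, meal_time_min = meal_time_min,
                 meal_duration_min = meal_duration_min,
                 study_end_min = study_end_min),
            class = "sampling_schedule")
}

## ---- series ----------------------------------------------------------------

#' Concentration time series for one species
#'
#' Missing samples are `NA` and stay `NA`: they are masked, never imputed.
#'
#' @param species one of `r paste(CONC_SPECIES, collapse = ", ")`.
#' @param values numeric vector aligned with the schedule; `NA` = missing.
#' @export
concentration_series <- function(species, values) {
  species <- match.arg(species, CONC_SPECIES)
  values <- as.numeric(values)
  bad <- which(!is.na(values) & values < 0)
  if (length(bad))
    vldl_error(sprintf("negative %s concentration at row %d", species, bad[1]),
               "vldlkin_validation_error")
  structure(list(species = species, values = values),
            class = "concentration_series")
}

#' Tracer enrichment (MPE) time series for one pool
#'
#' @param pool one of `r paste(ENRICH_POOLS, collapse = ", ")`.
#' @param values molar percent excess per sample, in \[0, 100\]; `NA` = missing.
#' @export
enrichment_series <- function(pool, values) {
  pool <- match.arg(pool, ENRICH_POOLS)
  values <- as.numeric(values)
  bad <- which(!is.na(values) & (values < 0 | values > 100))
  if (length(bad))
    vldl_error(sprintf("MPE for %s out of [0, 100] at row %d", pool, bad[1]),
               "vldlkin_validation_error")
  structure(list(pool = pool, values = values), class = "enrichment_series")
}

## ---- protocol metadata -----------------------------------------------------

#' Tracer administration protocol
#'
#' Defaults follow the dual-bolus protocol: deuterated leucine 7 mg/kg body
#' weight and deuterated glycerol 500 mg total, given at time 0.
#' @param leucine_dose mg per kg body weight.
#' @param glycerol_dose mg (total).
#' @param administration_time_min minutes (0 = study start).
#' @export
tracer_protocol <- function(leucine_dose = 7, glycerol_dose = 500,
                            administration_time_min = 0) {
  # zero dose = no tracer given (all predicted enrichments identically 0)
  if (leucine_dose < 0 || glycerol_dose < 0)
    vldl_error("tracer doses must be >= 0", "vldlkin_validation_error")
  structure(list(leucine_dose = leucine_dose, glycerol_dose = glycerol_dose,
                 administration_time_min = administration_time_min),
            class = "tracer_protocol")
}

#' Mixed-meal composition
#'
#' Defaults approximate the liquid test meal (two protein-energy drinks plus
#' 40 mL olive oil): about 60 g triglyceride and 40 g protein.
#' @param tg_content g of triglyceride in the meal.
#' @param protein_content g of protein.
#' @param ingestion_duration_min minutes taken to consume the meal.
#' @export
meal_spec <- function(tg_content = 60, protein_content = 40,
                      ingestion_duration_min = 10) {
  if (tg_content <= 0)
    vldl_error("tg_content must be > 0", "vldlkin_validation_error")
  if (ingestion_duration_min <= 0)
    vldl_error("ingestion_duration_min must be > 0", "vldlkin_validation_error")
  structure(list(tg_content = tg_content, protein_content = protein_content,
                 ingestion_duration_min = ingestion_duration_min),
            class = "meal_spec")
}

#' Two-step hyperinsulinemic-euglycemic clamp record
#'
#' Time series are sampled on `time_min`; `step` labels each row as
#' `basal`, `step1` or `step2`. Tracer-to-tracee ratios (TTR) are
#' dimensionless; use [mpe_to_ttr()] when converting from MPE.
#'
#' @param time_min sample times (minutes from clamp start).
#' @param step character vector: `basal`/`step1`/`step2` per row.
#' @param glucose_conc mmol/L.
#' @param glucose_ttr dimensionless.
#' @param glycerol_conc µmol/L.
#' @param glycerol_ttr dimensionless.
#' @param exo_glucose_infusion µmol/kg/min exogenous glucose infusion.
#' @param basal_insulin,step1_insulin,step2_insulin mU/L plateau insulin.
#' @param glucose_tracer_rate,glycerol_tracer_rate µmol/kg/min continuous
#'   tracer infusion rates (protocol: 0.11 each).
#' @export
clamp_record <- function(time_min, step, glucose_conc, glucose_ttr,
                         glycerol_conc, glycerol_ttr, exo_glucose_infusion,
                         basal_insulin, step1_insulin, step2_insulin,
                         glucose_tracer_rate = 0.11,
                         glycerol_tracer_rate = 0.11) {
  if (glucose_tracer_rate <= 0 || glycerol_tracer_rate <= 0)
    vldl_error("tracer infusion rates must be > 0", "vldlkin_validation_error")
  if (!(step2_insulin > step1_insulin && step1_insulin > basal_insulin))
    vldl_error("insulin plateaus must satisfy step2 > step1 > basal",
               "vldlkin_validation_error")
  if (any(glucose_ttr < 0, na.rm = TRUE) || any(glycerol_ttr < 0, na.rm = TRUE))
    vldl_error("TTR must be >= 0", "vldlkin_validation_error")
  step <- match.arg(step, c("basal", "step1", "step2"), several.ok = TRUE)
  structure(list(time_min = as.numeric(time_min), step = step,
                 glucose_conc = as.numeric(glucose_conc),
                 glucose_ttr = as.numeric(glucose_ttr),
                 glycerol_conc = as.numeric(glycerol_conc),
                 glycerol_ttr = as.numeric(glycerol_ttr),
                 exo_glucose_infusion = as.numeric(exo_glucose_infusion),
                 basal_insulin = basal_insulin, step1_insulin = step1_insulin,
                 step2_insulin = step2_insulin,
                 glucose_tracer_rate = glucose_tracer_rate,
                 glycerol_tracer_rate = glycerol_tracer_rate),
            class = "clamp_record")
}

## ---- patient dataset -------------------------------------------------------

#' One subject-condition's full observed dataset
#'
#' @param patient_id identifier string.
#' @param condition `"pre"` or `"post"` (surgery).
#' @param body_weight kg.
#' @param height m.
#' @param schedule [sampling_schedule()].
#' @param concentrations named list of [concentration_series()], one per
#'   species in the fixed vocabulary.
#' @param enrichments named list of [enrichment_series()], one per pool.
#' @param meal [meal_spec()].
#' @param tracer [tracer_protocol()].
#' @param fasting_glucose mmol/L.
#' @param fasting_insulin mU/L.
#' @param clamp optional [clamp_record()].
#' @return object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, condition, body_weight, height,
                            schedule, concentrations, enrichments,
                            meal = meal_spec(), tracer = tracer_protocol(),
                            fasting_glucose = NA_real_,
                            fasting_insulin = NA_real_, clamp = NULL) {
  condition <- match.arg(condition, c("pre", "post"))
  if (body_weight <= 0)
    vldl_error("body_weight must be > 0", "vldlkin_validation_error")
  if (!inherits(schedule, "sampling_schedule"))
    vldl_error("schedule must be a sampling_schedule", "vldlkin_schema_error")
  nt <- length(schedule$times_min)

  names(concentrations) <- vapply(concentrations, `[[`, "", "species")
  names(enrichments) <- vapply(enrichments, `[[`, "", "pool")
  for (sp in CONC_SPECIES)
    if (sum(names(concentrations) == sp) != 1L)
      vldl_error(sprintf("species %s must be present exactly once", sp),
                 "vldlkin_schema_error")
  for (pl in ENRICH_POOLS)
    if (sum(names(enrichments) == pl) != 1L)
      vldl_error(sprintf("enrichment pool %s must be present exactly once", pl),
                 "vldlkin_schema_error")
  for (s in c(concentrations, enrichments))
    if (length(s$values) != nt)
      vldl_error(sprintf("series %s length %d != schedule length %d",
                         c(s$species, s$pool)[1], length(s$values), nt),
                 "vldlkin_validation_error")
  if (!is.na(fasting_glucose) && fasting_glucose < 0)
    vldl_error("fasting_glucose must be >= 0", "vldlkin_validation_error")
  if (!is.na(fasting_insulin) && fasting_insulin < 0)
    vldl_error("fasting_insulin must be >= 0", "vldlkin_validation_error")

  structure(list(patient_id = as.character(patient_id), condition = condition,
                 body_weight = body_weight, height = height,
                 schedule = schedule,
                 concentrations = concentrations[CONC_SPECIES],
                 enrichments = enrichments[ENRICH_POOLS],
                 meal = meal, tracer = tracer,
                 fasting_glucose = fasting_glucose,
                 fasting_insulin = fasting_insulin, clamp = clamp),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> %s [%s], %.1f kg, %d samples (%g-%g min)\n",
              x$patient_id, x$condition, x$body_weight,
              length(x$schedule$times_min), min(x$schedule$times_min),
              max(x$schedule$times_min)))
  cat(sprintf("  meal: %.0f g TG at %g min over %g min; clamp: %s\n",
              x$meal$tg_content, x$schedule$meal_time_min,
              x$meal$ingestion_duration_min,
              if (is.null(x$clamp)) "absent" else "present"))
  invisible(x)
}

#' Convert between molar percent excess and tracer-to-tracee ratio
#'
#' `TTR = MPE / (100 - MPE)`; the inverse is `MPE = 100 TTR / (1 + TTR)`.
#' @param mpe molar percent excess (%).
#' @export
mpe_to_ttr <- function(mpe) mpe / (100 - mpe)

#' @rdname mpe_to_ttr
#' @param ttr tracer-to-tracee ratio (dimensionless).
#' @export
ttr_to_mpe <- function(ttr) 100 * ttr / (1 + ttr)
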