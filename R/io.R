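## Reading and writing patient datasets.
##
## On-disk layout: one data CSV per patient-condition plus a JSON metadata
## sidecar (`<stem>_meta.json`). The CSV comes in two accepted dialects:
##   long:  time_min, variable, value      (written by default)
##   wide:  time_min, <one column per variable>
## `variable` is drawn from the fixed species/pool vocabulary. Missing
## samples are empty cells, never zeros, and are masked on read.

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_meta.json")
}

#' Write a patient dataset to disk
#'
#' Writes the time-series data as a long-format CSV (`time_min, variable,
#' value`) and the metadata (id, condition, anthropometry, meal, tracer,
#' schedule, fasting values, clamp) as a JSON sidecar next to it. The round
#' trip through [read_patient_dataset()] is lossless, including missing-value
#' masks.
#'
#' @param dataset a [patient_dataset()].
#' @param path CSV file path; the sidecar is written to `<stem>_meta.json`.
#' @param format `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_patient_dataset <- function(dataset, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "patient_dataset"))
  tm <- dataset$schedule$times_min
  vals <- c(lapply(dataset$concentrations, `[[`, "values"),
            lapply(dataset$enrichments, `[[`, "values"))
  if (format == "long") {
    df <- data.frame(
      time_min = rep(tm, times = length(vals)),
      variable = rep(names(vals), each = length(tm)),
      value = unlist(vals, use.names = FALSE))
  } else {
    df <- cbind(data.frame(time_min = tm), as.data.frame(vals))
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    vldl_error(sprintf("cannot write dataset to '%s'", path),
               "vldlkin_io_error")

  meta <- list(
    patient_id = dataset$patient_id, condition = dataset$condition,
    body_weight = dataset$body_weight, height = dataset$height,
    fasting_glucose = dataset$fasting_glucose,
    fasting_insulin = dataset$fasting_insulin,
    schedule = unclass(dataset$schedule),
    meal = unclass(dataset$meal),
    tracer = unclass(dataset$tracer),
    clamp = if (!is.null(dataset$clamp)) unclass(dataset$clamp))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a patient dataset from disk
#'
#' Accepts the long dialect (`time_min, variable, value`) or the wide dialect
#' (`time_min` plus one column per variable). All type invariants are
#' enforced at read time; empty cells become masked (`NA`) samples.
#'
#' @param path CSV file written by [write_patient_dataset()] (or conforming
#'   to the documented dialect, with its `<stem>_meta.json` sidecar).
#' @param condition optional override of the sidecar condition label.
#' @return a validated [patient_dataset()].
#' @export
read_patient_dataset <- function(path, condition = NULL) {
  if (!file.exists(path))
    vldl_error(sprintf("file '%s' does not exist", path), "vldlkin_io_error")
  mp <- sidecar_path(path)
  if (!file.exists(mp))
    vldl_error(sprintf("metadata sidecar '%s' does not exist", mp),
               "vldlkin_io_error")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)

  if ("variable" %in% names(df)) {
    for (col in c("time_min", "variable", "value"))
      if (!col %in% names(df))
        vldl_error(sprintf("missing required column '%s'", col),
                   "vldlkin_schema_error")
    tm <- sort(unique(df$time_min))
    series <- lapply(split(df, df$variable), function(d) {
      d$value[match(tm, d$time_min)]
    })
  } else {
    if (!"time_min" %in% names(df))
      vldl_error("missing required column 'time_min'", "vldlkin_schema_error")
    tm <- df$time_min
    if (any(diff(tm) <= 0))
      vldl_error("time grid is not strictly increasing",
                 "vldlkin_validation_error")
    series <- as.list(df[setdiff(names(df), "time_min")])
  }
  for (v in c(CONC_SPECIES, ENRICH_POOLS))
    if (!v %in% names(series))
      vldl_error(sprintf("missing required column '%s'", v),
                 "vldlkin_schema_error")

  sched <- sampling_schedule(
    times_min = tm,
    meal_time_min = meta$schedule$meal_time_min,
    meal_duration_min = meta$schedule$meal_duration_min,
    study_end_min = meta$schedule$study_end_min)
  clamp <- NULL
  if (!is.null(meta$clamp))
    clamp <- do.call(clamp_record, meta$clamp[c(
      "time_min", "step", "glucose_conc", "glucose_ttr", "glycerol_conc",
      "glycerol_ttr", "exo_glucose_infusion", "basal_insulin",
      "step1_insulin", "step2_insulin", "glucose_tracer_rate",
      "glycerol_tracer_rate")])

  patient_dataset(
    patient_id = meta$patient_id,
    condition = if (is.null(condition)) meta$condition else condition,
    body_weight = meta$body_weight, height = meta$height,
    schedule = sched,
    concentrations = lapply(CONC_SPECIES, function(sp)
      concentration_series(sp, series[[sp]])),
    enrichments = lapply(ENRICH_POOLS, function(pl)
      enrichment_series(pl, series[[pl]])),
    meal = do.call(meal_spec, meta$meal),
    tracer = do.call(tracer_protocol, meta$tracer),
    fasting_glucose = if (is.null(meta$fasting_glucose)) NA_real_ else
      meta$fasting_glucose,
    fasting_insulin = if (is.null(meta$fasting_insulin)) NA_real_ else
      meta$fasting_insulin,
    clamp = clamp)
}

#' Write a whole cohort of datasets
#'
#' File names are deterministic: `<id>_<condition>.csv` under `dir`.
#' @param datasets list of [patient_dataset()] objects.
#' @param dir output directory (created if absent).
#' @return character vector of written CSV paths, invisibly.
#' @export
write_cohort <- function(datasets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(datasets, function(d)
    file.path(dir, sprintf("%s_%s.csv", d$patient_id, d$condition)), "")
  for (i in seq_along(datasets)) write_patient_dataset(datasets[[i]], paths[i])
  invisible(paths)
}
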