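## Derived per-patient kinetic quantities: postprandial AUCs, peak times,
## TG:apoB ratios, total/direct production splits, FCR identities.

#' Postprandial area under the concentration curve
#'
#' Trapezoidal integral over the non-missing samples inside the window
#' (default 2-10 h, the postprandial window: meal at 2 h, last daytime
#' sample at 10 h), in mg.h/dL. Missing samples are excluded, not
#' interpolated; fewer than 2 usable samples give `NA` (metric undefined),
#' never zero.
#'
#' @param series a [concentration_series()].
#' @param schedule the [sampling_schedule()].
#' @param window `c(start_h, end_h)`.
#' @return AUC in mg.h/dL (or `NA_real_`).
#' @export
compute_auc <- function(series, schedule, window = c(2, 10)) {
  th <- schedule$times_min / 60
  keep <- th >= window[1] & th <= window[2] & !is.na(series$values)
  if (sum(keep) < 2) return(NA_real_)
  x <- th[keep]
  y <- series$values[keep]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Time of the postprandial concentration peak
#'
#' Sample time (hours) of the maximum observed value inside the window;
#' earliest time on ties. Computed on the observed grid, not a fitted curve.
#'
#' @inheritParams compute_auc
#' @return peak time in hours (or `NA_real_` if the window is empty).
#' @export
peak_time <- function(series, schedule, window = c(2, 10)) {
  th <- schedule$times_min / 60
  keep <- th >= window[1] & th <= window[2] & !is.na(series$values)
  if (!any(keep)) return(NA_real_)
  x <- th[keep]
  y <- series$values[keep]
  x[which.max(y)]
}

#' TG to apoB AUC ratio
#'
#' Average particle TG load proxy: the ratio of the TG to apoB postprandial
#' AUCs of one VLDL fraction, mg TG per mg apoB.
#'
#' @param auc_tg,auc_apob AUCs in mg.h/dL.
#' @export
tg_apob_ratio <- function(auc_tg, auc_apob) {
  if (is.na(auc_apob) || auc_apob <= 0) return(NA_real_)
  auc_tg / auc_apob
}

#' Per-patient percent change
#'
#' `100 (post - pre) / pre`, per patient; `NA` (undefined) at zero baseline.
#' @param pre,post scalars or aligned vectors.
#' @export
percent_change <- function(pre, post) {
  ifelse(is.na(pre) | pre == 0, NA_real_, 100 * (post - pre) / pre)
}

kinetic_summary_row <- function(params, dataset) {
  FCR <- fcr_v1(params)
  ss <- steady_state(params)
  sched <- dataset$schedule
  aucs <- vapply(c("V1B", "V2B", "V1TG", "V2TG", "CMTG", "PlasmaTG"),
                 function(sp) compute_auc(dataset$concentrations[[sp]], sched),
                 0)
  peaks <- vapply(c("V1B", "V2B", "V1TG", "V2TG", "CMTG", "PlasmaTG"),
                  function(sp) peak_time(dataset$concentrations[[sp]], sched),
                  0)
  homa <- if (!is.na(dataset$fasting_glucose) &&
              !is.na(dataset$fasting_insulin))
    homa_ir(dataset$fasting_glucose, dataset$fasting_insulin) else NA_real_
  data.frame(
    patient_id = dataset$patient_id, condition = dataset$condition,
    P_B1 = params$P_B1, P_B2d = params$P_B2d,
    P_B2_total = params$P_B2d + params$k_FTR_B * ss$masses[["V1B"]],
    P_T1 = params$P_T1, P_T2d = params$P_T2d,
    P_T2_total = params$P_T2d + params$k_FTR_T * ss$masses[["V1TG"]],
    FCR_B1 = unname(FCR["FCR_B1"]), k_FTR_B = params$k_FTR_B,
    k_FDC_B1 = params$k_FDC_B1, k_FCR_B2 = params$k_FCR_B2,
    FCR_T1 = unname(FCR["FCR_T1"]), k_FTR_T = params$k_FTR_T,
    k_FDC_T1 = params$k_FDC_T1, k_FCR_T2 = params$k_FCR_T2,
    k_CM = params$k_CM, f_abs = params$f_abs, ISI = params$ISI,
    pct_direct_B2 = 100 * params$P_B2d / (params$P_B1 + params$P_B2d),
    pct_direct_T2 = 100 * params$P_T2d / (params$P_T1 + params$P_T2d),
    auc_V1B = aucs[["V1B"]], auc_V2B = aucs[["V2B"]],
    auc_V1TG = aucs[["V1TG"]], auc_V2TG = aucs[["V2TG"]],
    auc_CMTG = aucs[["CMTG"]], auc_PlasmaTG = aucs[["PlasmaTG"]],
    peak_V1B = peaks[["V1B"]], peak_V2B = peaks[["V2B"]],
    peak_V1TG = peaks[["V1TG"]], peak_V2TG = peaks[["V2TG"]],
    peak_CMTG = peaks[["CMTG"]], peak_PlasmaTG = peaks[["PlasmaTG"]],
    tg_apob_V1 = tg_apob_ratio(aucs[["V1TG"]], aucs[["V1B"]]),
    tg_apob_V2 = tg_apob_ratio(aucs[["V2TG"]], aucs[["V2B"]]),
    homa_ir = homa,
    row.names = NULL)
}

#' Per-patient kinetic summary
#'
#' Combines the estimated rate parameters with the observed-series metrics:
#' `FCR_B1 = k_FTR_B + k_FDC_B1` (identity); total VLDL2 production = direct
#' secretion plus transfer inflow from the fasting VLDL1 pool
#' (`P_B2_total = P_B2d + k_FTR_B M_V1B`); percent of hepatic secretion as
#' VLDL2 = `100 P_B2d / (P_B1 + P_B2d)`; postprandial AUCs, peak times and
#' TG:apoB ratios from the observed grid; HOMA-IR from fasting values.
#'
#' @param fit a converged [fit_patient()] result.
#' @param dataset the fitted [patient_dataset()].
#' @return one-row data.frame (class `kinetic_summary`).
#' @export
derive_kinetics <- function(fit, dataset) {
  if (!isTRUE(fit$converged) && fit$objective >= PENALTY)
    vldl_error("fit did not converge; refusing to summarise",
               "vldlkin_estimation_error")
  out <- kinetic_summary_row(fit$params, dataset)
  class(out) <- c("kinetic_summary", class(out))
  out
}

#' Ground-truth kinetic summary (no fit)
#'
#' Same summary as [derive_kinetics()] computed directly from known
#' parameters, for synthetic-cohort validation.
#' @param params a [model_parameters()].
#' @param dataset the corresponding [patient_dataset()].
#' @export
true_kinetics <- function(params, dataset) {
  out <- kinetic_summary_row(params, dataset)
  class(out) <- c("kinetic_summary", class(out))
  out
}
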