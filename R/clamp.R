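## Hyperinsulinemic-euglycemic clamp fluxes (Steele equations) and
## tissue-specific insulin sensitivity indices.
##
## Conventions: tracer infusion F and fluxes in µmol/kg/min; enrichment as
## tracer-to-tracee ratio (TTR); pV is the Steele pool fraction times the
## distribution volume (L/kg), defaults 0.65 x 0.16 for glucose and
## 0.65 x 0.23 for glycerol.

PV_GLUCOSE <- 0.65 * 0.16
PV_GLYCEROL <- 0.65 * 0.23

#' Steady-state Steele equation
#'
#' Rate of appearance of the tracee from isotope dilution at plateau:
#' `Ra = F / TTR`.
#'
#' @param F tracer infusion rate, µmol/kg/min.
#' @param TTR tracer-to-tracee ratio at plateau (> 0).
#' @return Ra in µmol/kg/min.
#' @export
steele_steady <- function(F, TTR) {
  if (any(TTR <= 0))
    vldl_error("TTR must be > 0", "vldlkin_domain_error")
  F / TTR
}

#' Non-steady-state Steele equations over a sampling interval
#'
#' `Ra = (F - pV * Cbar * dE/dt) / Ebar`; `Rd = Ra - pV * dC/dt`;
#' `EGP = Ra - exogenous infusion`. With vanishing derivatives this reduces
#' exactly to the steady-state form.
#'
#' @param F tracer infusion, µmol/kg/min.
#' @param conc `c(C1, C2)` tracee concentration at `t1`, `t2` (µmol/L).
#' @param ttr `c(E1, E2)` TTR at the same times.
#' @param times `c(t1, t2)` in minutes, `t2 > t1`.
#' @param pV pool fraction x distribution volume, L/kg.
#' @param exo_infusion exogenous tracee infusion, µmol/kg/min.
#' @return list with `Ra`, `Rd`, `EGP` (µmol/kg/min).
#' @export
steele_nonsteady <- function(F, conc, ttr, times, pV, exo_infusion = 0) {
  if (times[2] <= times[1])
    vldl_error("times must be increasing", "vldlkin_domain_error")
  Ebar <- mean(ttr)
  if (Ebar <= 0)
    vldl_error("mean TTR must be > 0", "vldlkin_domain_error")
  dt <- times[2] - times[1]
  dE <- (ttr[2] - ttr[1]) / dt       # per min
  dC <- (conc[2] - conc[1]) / dt     # µmol/L/min
  # pV (L/kg) x conc (µmol/L) x rate (1/min) -> µmol/kg/min
  Ra <- (F - pV * mean(conc) * dE) / Ebar
  Rd <- Ra - pV * dC
  list(Ra = Ra, Rd = Rd, EGP = Ra - exo_infusion)
}

#' Percent suppression / stimulation of a flux by hyperinsulinemia
#'
#' Suppression: `100 (basal - clamped) / basal` (hepatic EGP by step 1,
#' adipose lipolysis by step 1). Stimulation: `100 (clamped - basal) /
#' basal` (muscle glucose disposal by step 2).
#'
#' @param basal,clamped fluxes in µmol/kg/min; `basal > 0`.
#' @export
suppression_index <- function(basal, clamped) {
  if (is.na(basal) || basal == 0) return(NA_real_)
  100 * (basal - clamped) / basal
}

#' @rdname suppression_index
#' @export
stimulation_index <- function(basal, clamped) {
  if (is.na(basal) || basal == 0) return(NA_real_)
  100 * (clamped - basal) / basal
}

#' Normalize a clamp index by the fractional insulin increase
#'
#' Divides an index (% change of a flux) by the fractional rise of insulin
#' over basal during that clamp step, `(I_clamp - I_basal)/I_basal`, making
#' indices comparable across subjects with different insulin clearance.
#'
#' @param index percent suppression/stimulation.
#' @param I_basal,I_clamp insulin, mU/L, `I_clamp > I_basal > 0`.
#' @return index per unit fractional insulin increase.
#' @export
normalize_by_insulin <- function(index, I_basal, I_clamp) {
  if (I_basal <= 0 || I_clamp <= I_basal)
    vldl_error("need I_clamp > I_basal > 0", "vldlkin_domain_error")
  index / ((I_clamp - I_basal) / I_basal)
}

#' Homeostatic model assessment of insulin resistance
#'
#' `HOMA-IR = fasting glucose (mmol/L) x fasting insulin (mU/L) / 22.5`.
#' @param fasting_glucose mmol/L.
#' @param fasting_insulin mU/L.
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose < 0, fasting_insulin < 0, na.rm = TRUE))
    vldl_error("fasting values must be >= 0", "vldlkin_domain_error")
  fasting_glucose * fasting_insulin / 22.5
}

#' Excess body weight over the BMI-25 reference
#'
#' The weight corresponding to the difference between the patient's BMI and
#' a cutoff of 25 kg/m^2: `weight - 25 height^2`. May be negative (reported
#' as is).
#' @param weight kg.
#' @param height m (> 0).
#' @export
excess_weight <- function(weight, height) {
  if (any(height <= 0))
    vldl_error("height must be > 0", "vldlkin_domain_error")
  weight - 25 * height^2
}

# plateau means over the last `window` minutes of one clamp step
plateau <- function(rec, step, window = 30) {
  i <- rec$step == step
  tmax <- max(rec$time_min[i])
  j <- i & rec$time_min >= tmax - window
  list(glucose_conc = mean(rec$glucose_conc[j]),
       glucose_ttr = mean(rec$glucose_ttr[j]),
       glycerol_conc = mean(rec$glycerol_conc[j]),
       glycerol_ttr = mean(rec$glycerol_ttr[j]),
       gir = mean(rec$exo_glucose_infusion[j]),
       t = range(rec$time_min[j]),
       glucose_first_last = rec$glucose_conc[j][c(1, sum(j))],
       glucose_ttr_first_last = rec$glucose_ttr[j][c(1, sum(j))],
       glycerol_conc_first_last = rec$glycerol_conc[j][c(1, sum(j))],
       glycerol_ttr_first_last = rec$glycerol_ttr[j][c(1, sum(j))])
}

#' Summarise a clamp study into insulin sensitivity indices
#'
#' Basal fluxes from the steady-state Steele equation on the basal plateau;
#' step fluxes from the non-steady-state form averaged over the last 30
#' minutes of each step. Hepatic sensitivity = % EGP suppression by step 1;
#' adipose = % lipolysis (glycerol Ra) suppression by step 1; peripheral =
#' % glucose Rd stimulation by step 2; each also normalised by that step's
#' fractional insulin increase. HOMA-IR and excess weight are included when
#' the dataset carries fasting values and anthropometry.
#'
#' @param dataset a [patient_dataset()] whose `clamp` field is a
#'   [clamp_record()], or a bare [clamp_record()].
#' @param plateau_window minutes of each step treated as plateau (30).
#' @return one-row data.frame (class `clamp_summary`).
#' @export
clamp_summary <- function(dataset, plateau_window = 30) {
  rec <- if (inherits(dataset, "clamp_record")) dataset else dataset$clamp
  if (is.null(rec))
    vldl_error("no clamp record available", "vldlkin_validation_error")
  pb <- plateau(rec, "basal", plateau_window)
  p1 <- plateau(rec, "step1", plateau_window)
  p2 <- plateau(rec, "step2", plateau_window)
  Fg <- rec$glucose_tracer_rate
  Fy <- rec$glycerol_tracer_rate

  basal_EGP <- steele_steady(Fg, pb$glucose_ttr) - pb$gir
  basal_lip <- steele_steady(Fy, pb$glycerol_ttr)

  ns <- function(p, F, what, pV) {
    conc <- if (what == "glucose") p$glucose_first_last * 1000 else
      p$glycerol_conc_first_last
    ttr <- if (what == "glucose") p$glucose_ttr_first_last else
      p$glycerol_ttr_first_last
    steele_nonsteady(F, conc, ttr, p$t, pV,
                     exo_infusion = if (what == "glucose") p$gir else 0)
  }
  s1_glu <- ns(p1, Fg, "glucose", PV_GLUCOSE)
  s2_glu <- ns(p2, Fg, "glucose", PV_GLUCOSE)
  s1_gly <- ns(p1, Fy, "glycerol", PV_GLYCEROL)

  EGP_supp <- suppression_index(basal_EGP, s1_glu$EGP)
  lip_supp <- suppression_index(basal_lip, s1_gly$Ra)
  Rd_stim <- stimulation_index(basal_EGP + pb$gir, s2_glu$Rd)

  out <- data.frame(
    basal_EGP = basal_EGP, basal_lipolysis = basal_lip,
    EGP_suppression = EGP_supp, lipolysis_suppression = lip_supp,
    Rd_stimulation = Rd_stim,
    EGP_suppression_norm = normalize_by_insulin(
      EGP_supp, rec$basal_insulin, rec$step1_insulin),
    lipolysis_suppression_norm = normalize_by_insulin(
      lip_supp, rec$basal_insulin, rec$step1_insulin),
    Rd_stimulation_norm = normalize_by_insulin(
      Rd_stim, rec$basal_insulin, rec$step2_insulin),
    row.names = NULL)
  if (!inherits(dataset, "clamp_record")) {
    out$patient_id <- dataset$patient_id
    out$condition <- dataset$condition
    out$HOMA_IR <- if (!is.na(dataset$fasting_glucose) &&
                       !is.na(dataset$fasting_insulin))
      homa_ir(dataset$fasting_glucose, dataset$fasting_insulin) else NA_real_
    out$excess_weight <- excess_weight(dataset$body_weight, dataset$height)
  }
  class(out) <- c("clamp_summary", class(out))
  out
}
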