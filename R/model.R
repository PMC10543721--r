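## Forward model: parameter/state plumbing around the compiled ODE core.
##
## Internal units are mg per kg body weight for masses and days for time;
## user-facing times are minutes (sampling grid) or hours (reports).

W_V2 <- 0.5  # fixed VLDL2 competition weight (size ordering w_CM >= 1 >= w_V2)

# 1-based indices into one block of the C++ state vector
state_index <- function(n_delay) {
  n <- n_delay
  list(stomach = 1L, gut = 2L, cm_chain = 3L:(n + 2L), cm = n + 3L,
       b1_chain = (n + 4L):(2L * n + 3L), b2_chain = (2L * n + 4L):(3L * n + 3L),
       t1_chain = (3L * n + 4L):(4L * n + 3L), t2_chain = (4L * n + 4L):(5L * n + 3L),
       pB1 = 5L * n + 4L, pB2 = 5L * n + 5L, pT1 = 5L * n + 6L,
       pT2 = 5L * n + 7L, block = 5L * n + 7L)
}

k_chain_per_day <- function(params) 24 * params$n_delay / params$tau_sec

#' Meal TG delivery flux into the stomach
#'
#' Zero-order (boxcar) delivery: the meal's TG enters the stomach pool at a
#' constant rate over the ingestion window and the time-integral equals the
#' total meal TG per kg body weight.
#'
#' @param t time, minutes post tracer (vectorized).
#' @param meal a [meal_spec()].
#' @param schedule the [sampling_schedule()] (provides meal start).
#' @param body_weight kg.
#' @return flux in mg/kg per hour.
#' @export
meal_input_flux <- function(t, meal, schedule, body_weight) {
  t0 <- schedule$meal_time_min
  t1 <- t0 + meal$ingestion_duration_min
  rate <- meal$tg_content * 1000 / body_weight / (meal$ingestion_duration_min / 60)
  ifelse(t >= t0 & t < t1, rate, 0)
}

#' Plasma precursor enrichment forcing
#'
#' Multi-exponential decay `MPE(t) = sum_i A_i exp(-lambda_i t)` fitted to
#' the measured plasma leucine or glycerol MPE after the tracer bolus; it
#' drives the labeled fraction of hepatic synthesis fluxes.
#'
#' @param t minutes post tracer (vectorized).
#' @param coefficients `list(A = , lambda = )`, `A` in MPE %, `lambda` 1/min.
#' @return MPE in %.
#' @export
precursor_enrichment <- function(t, coefficients) {
  A <- coefficients$A
  lam <- coefficients$lambda
  if (any(A < 0) || any(lam <= 0))
    vldl_error("precursor coefficients must be non-negative with lambda > 0",
               "vldlkin_domain_error")
  rowSums(exp(outer(t, lam, function(tt, ll) -ll * tt)) *
            rep(A, each = length(t)))
}

#' Shared-capacity competition factor for lipolysis
#'
#' All TG-rich particles compete for LPL: each lipolytic flux is scaled by
#' `K_lip / (K_lip + w_CM * TG_CM + TG_V1 + w_V2 * TG_V2)` with size-ordered
#' weights `w_CM = w_comp >= w_V1 = 1 >= w_V2 = 0.5`. The factor tends to 1
#' as total TG mass vanishes and decreases as chylomicron TG floods in.
#' Inside the simulator the factor is normalised to its fasting steady-state
#' value, so the estimated fractional rates are fasting-referenced.
#'
#' @param tg_masses named numeric: TG masses `CM`, `V1`, `V2` in mg/kg.
#' @param params a [model_parameters()].
#' @return named per-pool factors in (0, 1\].
#' @export
competition_factor <- function(tg_masses, params) {
  if (any(tg_masses < 0))
    vldl_error("TG masses must be non-negative", "vldlkin_domain_error")
  s <- params$w_comp * tg_masses[["CM"]] + tg_masses[["V1"]] +
    W_V2 * tg_masses[["V2"]]
  f <- params$K_lip / (params$K_lip + s)
  c(CM = f, V1 = f, V2 = f)
}

#' Fasting steady state of the model
#'
#' Unlabeled plasma masses satisfy flux balance (`M_V1B = P_B1 / FCR_B1`,
#' `M_V2B = (P_B2d + k_FTR_B M_V1B) / k_FCR_B2`, analogously for TG); the
#' hepatic secretion-delay chains carry their through-flux mass
#' `P / k_chain`; meal-path pools and all labeled pools are empty.
#'
#' @param params a [model_parameters()].
#' @param I_b basal insulin (mU/L); at the fasting point the insulin
#'   multiplier is 1, so `I_b` does not alter the balance but is recorded.
#' @return object of class `model_state`: full state vector plus named
#'   plasma masses and the fasting competition factor `fc_ss`.
#' @export
steady_state <- function(params, I_b = 10) {
  validate_model_parameters(params)
  FCR <- fcr_v1(params)
  bal <- function(P, k, what) {
    if (P > 0 && k <= 0)
      vldl_error(sprintf("no steady state: %s has production but zero removal",
                         what), "vldlkin_domain_error")
    if (P <= 0) 0 else P / k
  }
  M_B1 <- bal(params$P_B1, FCR[["FCR_B1"]], "VLDL1 apoB")
  M_T1 <- bal(params$P_T1, FCR[["FCR_T1"]], "VLDL1 TG")
  in_B2 <- params$P_B2d + params$k_FTR_B * M_B1
  in_T2 <- params$P_T2d + params$k_FTR_T * M_T1
  M_B2 <- bal(in_B2, params$k_FCR_B2, "VLDL2 apoB")
  M_T2 <- bal(in_T2, params$k_FCR_T2, "VLDL2 TG")

  idx <- state_index(params$n_delay)
  kch <- k_chain_per_day(params)
  y <- numeric(2L * idx$block)
  y[idx$b1_chain] <- params$P_B1 / kch
  y[idx$b2_chain] <- params$P_B2d / kch
  y[idx$t1_chain] <- params$P_T1 / kch
  y[idx$t2_chain] <- params$P_T2d / kch
  y[idx$pB1] <- M_B1
  y[idx$pB2] <- M_B2
  y[idx$pT1] <- M_T1
  y[idx$pT2] <- M_T2

  fc_ss <- unname(competition_factor(c(CM = 0, V1 = M_T1, V2 = M_T2),
                                     params)[1])
  structure(list(state = y, n_delay = params$n_delay,
                 masses = c(V1B = M_B1, V2B = M_B2, V1TG = M_T1, V2TG = M_T2),
                 fc_ss = fc_ss, I_b = I_b),
            class = "model_state")
}

# assemble the flat parameter list consumed by the C++ core
cpp_pars <- function(params, schedule, meal, tracer, forcing, body_weight,
                     fc_ss) {
  no_meal <- is.null(meal)
  if (no_meal) meal <- meal_spec()  # placeholder; rate forced to 0 below
  dur <- meal$ingestion_duration_min
  list(
    n_delay = params$n_delay,
    k_ge_d = 24 * params$k_ge,
    k_chain_d = k_chain_per_day(params),
    P_B1 = params$P_B1, P_B2d = params$P_B2d,
    P_T1 = params$P_T1, P_T2d = params$P_T2d,
    k_FTR_B = params$k_FTR_B, k_FDC_B1 = params$k_FDC_B1,
    k_FCR_B2 = params$k_FCR_B2, k_FTR_T = params$k_FTR_T,
    k_FDC_T1 = params$k_FDC_T1, k_FCR_T2 = params$k_FCR_T2,
    k_CM = params$k_CM, f_abs = params$f_abs, ISI = params$ISI,
    I_b = forcing$I_b, w_cm = params$w_comp, w_v2 = W_V2,
    K_lip = params$K_lip, fc_ss = fc_ss,
    meal_t0_d = schedule$meal_time_min / 1440,
    meal_t1_d = (schedule$meal_time_min + dur) / 1440,
    meal_rate = if (no_meal) 0 else
      meal$tg_content * 1000 / body_weight / (dur / 1440),
    A_leu = params$precursor_leu$A,
    lam_leu_d = params$precursor_leu$lambda * 1440,
    A_gly = params$precursor_gly$A,
    lam_gly_d = params$precursor_gly$lambda * 1440,
    scale_leu = tracer$leucine_dose / 7,
    scale_gly = tracer$glycerol_dose / 500,
    ins_t_d = forcing$times_min / 1440,
    ins_y = forcing$values,
    ins_m_d = forcing$slopes * 1440)
}

#' Simulate the forward model
#'
#' Integrates the labeled + unlabeled ODE system from the fasting steady
#' state at t = 0 (tracer bolus drives the precursor forcing; the meal
#' enters as a boxcar; LPL-mediated fluxes are scaled by the insulin
#' multiplier times the normalised competition factor) and returns predicted
#' observables on the sampling grid plus dense trajectories.
#'
#' @param params a [model_parameters()].
#' @param schedule a [sampling_schedule()].
#' @param meal a [meal_spec()].
#' @param tracer a [tracer_protocol()].
#' @param forcing an [build_insulin_forcing()] result.
#' @param body_weight kg.
#' @param dense_dt_min spacing of the dense output grid (minutes).
#' @param rtol,atol integrator tolerances.
#' @param init_state optional `model_state` (or bare state vector) to start
#'   from instead of the fasting steady state; `meal = NULL` disables the
#'   meal input.
#' @return object of class `simulation_result` with fields `time_min`
#'   (dense grid), `states` (dense trajectory matrix), `schedule`,
#'   `concentrations` / `enrichments` (predicted series on the sampling
#'   grid) and `fluxes` (instantaneous lipolysis/transfer/clearance fluxes,
#'   mg/kg/d, on the sampling grid).
#' @export
simulate_model <- function(params, schedule, meal, tracer, forcing,
                           body_weight, dense_dt_min = 10,
                           rtol = 1e-8, atol = 1e-10, init_state = NULL) {
  ss <- steady_state(params, forcing$I_b)
  pl <- cpp_pars(params, schedule, meal, tracer, forcing, body_weight,
                 ss$fc_ss)
  if (!is.null(init_state)) {
    ss$state <- if (inherits(init_state, "model_state")) init_state$state
      else init_state
  }
  tm <- schedule$times_min
  dense <- unique(sort(c(seq(0, max(tm), by = dense_dt_min), tm)))
  res <- tryCatch(
    .simulate_cpp(pl, ss$state, dense / 1440, rtol, atol),
    error = function(e) {
      vldl_error(paste0("forward simulation failed: ", conditionMessage(e),
                        "\nparameters: ",
                        paste(sprintf("%s=%.4g", names(pl)[1:19],
                                      unlist(pl[1:19])), collapse = " ")),
                 "vldlkin_integration_error")
    })
  states <- res$states
  at <- match(tm, dense)
  obs <- observables(states[at, , drop = FALSE], params, body_weight)

  idx <- state_index(params$n_delay)
  tot <- function(i) states[at, i]      # first block carries total masses
  I <- forcing$fun(tm)
  phi <- lipolysis_multiplier(I, forcing$I_b, params$ISI)
  fc <- params$K_lip /
    (params$K_lip + params$w_comp * tot(idx$cm) + tot(idx$pT1) +
       W_V2 * tot(idx$pT2)) / ss$fc_ss
  lip <- phi * fc
  fluxes <- data.frame(
    time_min = tm,
    cm_clearance = params$k_CM * lip * tot(idx$cm),
    apoB_transfer = params$k_FTR_B * lip * tot(idx$pB1),
    tg_transfer = params$k_FTR_T * lip * tot(idx$pT1),
    v1_tg_lipolysis = params$k_FDC_T1 * lip * tot(idx$pT1),
    v2_tg_lipolysis = params$k_FCR_T2 * lip * tot(idx$pT2),
    lipolysis_multiplier = phi, competition_factor = fc * ss$fc_ss)

  structure(list(time_min = dense, states = states, schedule = schedule,
                 params = params, body_weight = body_weight,
                 concentrations = obs$concentrations,
                 enrichments = obs$enrichments, fluxes = fluxes,
                 steps = res$steps),
            class = "simulation_result")
}

#' Map state trajectories to predicted observables
#'
#' Concentration of a pool with mass M mg/kg in plasma volume `Vp` L/kg is
#' `M / (10 Vp)` mg/dL; MPE is `100 * labeled / (labeled + tracee)` =
#' 100 x labeled sub-mass over total pool mass, defined as 0 for an empty
#' pool. Total plasma TG is the sum of the VLDL1, VLDL2 and CM TG
#' concentrations.
#'
#' @param states trajectory matrix (rows = times, columns = state layout).
#' @param params a [model_parameters()].
#' @param body_weight kg (kept for interface symmetry; concentrations are
#'   per-kg masses over per-kg plasma volume, so it cancels).
#' @return list with named lists `concentrations` (mg/dL) and `enrichments`
#'   (MPE %), one numeric vector per species/pool.
#' @export
observables <- function(states, params, body_weight) {
  idx <- state_index(params$n_delay)
  m <- idx$block
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  u <- function(i) states[, i]          # total pool mass
  l <- function(i) states[, m + i]      # labeled sub-mass
  conc <- function(i) u(i) / (10 * params$Vp)
  mpe <- function(i) ifelse(u(i) > 0, 100 * l(i) / u(i), 0)
  concentrations <- list(
    V1B = conc(idx$pB1), V2B = conc(idx$pB2),
    V1TG = conc(idx$pT1), V2TG = conc(idx$pT2), CMTG = conc(idx$cm))
  concentrations$PlasmaTG <- concentrations$V1TG + concentrations$V2TG +
    concentrations$CMTG
  enrichments <- list(
    V1B_leu = mpe(idx$pB1), V2B_leu = mpe(idx$pB2),
    V1TG_gly = mpe(idx$pT1), V2TG_gly = mpe(idx$pT2))
  list(concentrations = concentrations, enrichments = enrichments)
}
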