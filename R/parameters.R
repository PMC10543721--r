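## Kinetic model parameters.

#' Kinetic model parameters
#'
#' All rate constants governing the forward model. Fractional catabolic rates
#' of the VLDL1 pools are identities, not free parameters:
#' `FCR_B1 = k_FTR_B + k_FDC_B1` and `FCR_T1 = k_FTR_T + k_FDC_T1`.
#'
#' @param P_B1 VLDL1 apoB production rate, mg/kg/d.
#' @param P_B2d VLDL2 apoB direct (hepatic) production rate, mg/kg/d.
#' @param P_T1 VLDL1 TG production rate, mg/kg/d.
#' @param P_T2d VLDL2 TG direct production rate, mg/kg/d.
#' @param k_FTR_B apoB fractional transfer rate VLDL1 -> VLDL2, pools/d.
#' @param k_FDC_B1 VLDL1 apoB fractional direct catabolic rate, pools/d.
#' @param k_FCR_B2 VLDL2 apoB fractional catabolic rate, pools/d.
#' @param k_FTR_T TG fractional transfer rate VLDL1 -> VLDL2, pools/d.
#' @param k_FDC_T1 VLDL1 TG fractional direct catabolic rate, pools/d.
#' @param k_FCR_T2 VLDL2 TG fractional catabolic rate, pools/d.
#' @param k_CM chylomicron TG fractional clearance rate, pools/d.
#' @param f_abs intestinal lipid absorption fraction, in \[0, 1\].
#' @param k_ge gastric emptying rate, 1/h.
#' @param tau_sec hepatic secretion delay time constant, h (whole chain).
#' @param n_delay number of Erlang delay sub-compartments (integer >= 1).
#' @param ISI lipoprotein-lipolysis insulin sensitivity index,
#'   dimensionless >= 0: LPL-mediated fluxes are multiplied by
#'   `1 + ISI * max(0, (I - I_b)/I_b)`.
#' @param Vp plasma volume, L/kg.
#' @param w_comp competition weight of CM TG relative to VLDL1 TG (= 1) in
#'   the shared-lipolysis saturation term; VLDL2 weight is fixed at 0.5 so
#'   that weights are ordered by particle size.
#' @param K_lip half-saturation TG mass of the shared lipolysis capacity,
#'   mg/kg.
#' @param precursor_leu,precursor_gly lists `list(A = , lambda = )` of
#'   multi-exponential plasma precursor MPE forcing coefficients; `A` in MPE
#'   %, `lambda` in 1/min.
#' @return object of class `model_parameters`.
#' @export
model_parameters <- function(P_B1 = 14, P_B2d = 6, P_T1 = 650, P_T2d = 100,
                             k_FTR_B = 3, k_FDC_B1 = 1.5, k_FCR_B2 = 3,
                             k_FTR_T = 10, k_FDC_T1 = 15, k_FCR_T2 = 11,
                             k_CM = 30, f_abs = 0.85, k_ge = 1.2,
                             tau_sec = 0.75, n_delay = 3, ISI = 0.2,
                             Vp = 0.045, w_comp = 3, K_lip = 300,
                             precursor_leu = list(A = c(5, 3),
                                                  lambda = c(0.05, 0.005)),
                             precursor_gly = list(A = c(6, 2),
                                                  lambda = c(0.08, 0.01))) {
  num <- as.numeric
  p <- list(P_B1 = num(P_B1), P_B2d = num(P_B2d), P_T1 = num(P_T1),
            P_T2d = num(P_T2d), k_FTR_B = num(k_FTR_B),
            k_FDC_B1 = num(k_FDC_B1), k_FCR_B2 = num(k_FCR_B2),
            k_FTR_T = num(k_FTR_T), k_FDC_T1 = num(k_FDC_T1),
            k_FCR_T2 = num(k_FCR_T2), k_CM = num(k_CM), f_abs = num(f_abs),
            k_ge = num(k_ge), tau_sec = num(tau_sec),
            n_delay = as.integer(n_delay), ISI = num(ISI), Vp = num(Vp),
            w_comp = num(w_comp), K_lip = num(K_lip),
            precursor_leu = lapply(precursor_leu[c("A", "lambda")], num),
            precursor_gly = lapply(precursor_gly[c("A", "lambda")], num))
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  rates <- c("P_B1", "P_B2d", "P_T1", "P_T2d", "k_FTR_B", "k_FDC_B1",
             "k_FCR_B2", "k_FTR_T", "k_FDC_T1", "k_FCR_T2", "k_CM", "k_ge",
             "tau_sec", "ISI", "Vp", "w_comp", "K_lip")
  for (r in rates)
    if (is.na(p[[r]]) || p[[r]] < 0)
      vldl_error(sprintf("parameter %s must be >= 0", r),
                 "vldlkin_validation_error")
  if (p$f_abs < 0 || p$f_abs > 1)
    vldl_error("f_abs must lie in [0, 1]", "vldlkin_validation_error")
  if (p$n_delay < 1L)
    vldl_error("n_delay must be >= 1", "vldlkin_validation_error")
  for (pc in list(p$precursor_leu, p$precursor_gly)) {
    if (any(pc$A < 0) || any(pc$lambda <= 0))
      vldl_error("precursor coefficients must have A >= 0, lambda > 0",
                 "vldlkin_validation_error")
    if (sum(pc$A) > 100)
      vldl_error("precursor amplitudes must sum to <= 100 MPE",
                 "vldlkin_validation_error")
  }
  invisible(p)
}

#' Derived fractional catabolic rates of the VLDL1 pools
#'
#' `FCR_B1 = k_FTR_B + k_FDC_B1`, `FCR_T1 = k_FTR_T + k_FDC_T1`.
#' @param params a [model_parameters()] object.
#' @return named numeric vector with `FCR_B1` and `FCR_T1`, pools/d.
#' @export
fcr_v1 <- function(params) {
  c(FCR_B1 = params$k_FTR_B + params$k_FDC_B1,
    FCR_T1 = params$k_FTR_T + params$k_FDC_T1)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  production (mg/kg/d): P_B1 %.3g  P_B2d %.3g  P_T1 %.3g  P_T2d %.3g\n",
              x$P_B1, x$P_B2d, x$P_T1, x$P_T2d))
  cat(sprintf("  apoB rates (pools/d): FTR %.3g  FDC1 %.3g  FCR2 %.3g\n",
              x$k_FTR_B, x$k_FDC_B1, x$k_FCR_B2))
  cat(sprintf("  TG rates (pools/d):   FTR %.3g  FDC1 %.3g  FCR2 %.3g  CM %.3g\n",
              x$k_FTR_T, x$k_FDC_T1, x$k_FCR_T2, x$k_CM))
  cat(sprintf("  f_abs %.3g  ISI %.3g  Vp %.3g L/kg  k_ge %.3g/h  tau_sec %.3g h (n=%d)\n",
              x$f_abs, x$ISI, x$Vp, x$k_ge, x$tau_sec, x$n_delay))
  invisible(x)
}

#' Serialize / deserialize model parameters
#'
#' Parameters are stored as JSON with explicit unit annotations.
#' @param params a [model_parameters()] object.
#' @param path file path.
#' @export
write_model_parameters <- function(params, path) {
  out <- unclass(params)
  out$units <- list(production = "mg/kg/d", fractional_rates = "pools/d",
                    k_ge = "1/h", tau_sec = "h", Vp = "L/kg",
                    K_lip = "mg/kg", precursor_lambda = "1/min")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_parameters
#' @export
read_model_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$units <- NULL
  x$precursor_leu <- as.list(x$precursor_leu)
  x$precursor_gly <- as.list(x$precursor_gly)
  do.call(model_parameters, x)
}
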