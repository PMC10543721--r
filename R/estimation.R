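## Per-patient parameter estimation: bound-constrained weighted least squares
## with seeded multi-start.
##
## The 13 free kinetic parameters are optimised on a transformed scale (log
## for positive rates/productions, linear for f_abs and ISI). Because apoB
## pools do not feed back on TG dynamics (lipolysis competition involves TG
## masses only), each start is explored in two stages -- TG/CM block against
## the TG observables, then the apoB block against the apoB observables --
## before a joint polish of the full objective. This is an efficiency device
## only; the reported objective is always the full weighted least squares.

FREE_PARAMS <- c("P_B1", "P_B2d", "P_T1", "P_T2d", "k_FTR_B", "k_FDC_B1",
                 "k_FCR_B2", "k_FTR_T", "k_FDC_T1", "k_FCR_T2", "k_CM",
                 "f_abs", "ISI")
LOG_PARAMS <- setdiff(FREE_PARAMS, c("f_abs", "ISI"))
TG_BLOCK <- c("P_T1", "P_T2d", "k_FTR_T", "k_FDC_T1", "k_FCR_T2", "k_CM",
              "f_abs", "ISI")
APOB_BLOCK <- c("P_B1", "P_B2d", "k_FTR_B", "k_FDC_B1", "k_FCR_B2")
FIT_CONC <- c("V1B", "V2B", "V1TG", "V2TG", "CMTG", "PlasmaTG")
FIT_ENR <- c("V1B_leu", "V2B_leu", "V1TG_gly", "V2TG_gly")
TG_SERIES <- c("V1TG", "V2TG", "CMTG", "PlasmaTG", "V1TG_gly", "V2TG_gly")
APOB_SERIES <- c("V1B", "V2B", "V1B_leu", "V2B_leu")

#' Default estimation bounds
#'
#' Generous envelopes around cohort-scale values. TG production runs to
#' 2000 mg/kg/d (of order 1 mg/kg/min, the upper end of measured VLDL-TG
#' secretion in severe obesity); fractional rates to 100 pools/d; ISI to 2;
#' f_abs in \[0.2, 1\].
#' @return named list of `c(lower, upper)` per free parameter.
#' @export
default_fit_bounds <- function() {
  list(P_B1 = c(1, 100), P_B2d = c(0.5, 50), P_T1 = c(50, 2000),
       P_T2d = c(5, 500), k_FTR_B = c(0.2, 50), k_FDC_B1 = c(0.1, 50),
       k_FCR_B2 = c(0.2, 50), k_FTR_T = c(0.5, 100), k_FDC_T1 = c(0.5, 100),
       k_FCR_T2 = c(0.5, 100), k_CM = c(2, 200), f_abs = c(0.2, 1),
       ISI = c(0, 2))
}

#' Estimation configuration
#'
#' @param n_starts number of multi-start points (seeded space-filling
#'   randomised-Halton set within bounds; nested in `n_starts`, so more
#'   starts can only improve the reachable objective).
#' @param bounds per-parameter `c(lower, upper)`; see [default_fit_bounds()].
#' @param weights objective class weights, named `concentration` and
#'   `enrichment`.
#' @param max_iterations optimiser iterations for the final joint polish.
#' @param explore_iterations iterations per start in the exploration stage.
#' @param seed RNG seed; identical seed/config/dataset give an identical fit.
#' @param rtol,rtol_polish ODE tolerances during exploration and polish.
#' @param structural named list of fixed structural parameters
#'   (`k_ge`, `tau_sec`, `n_delay`, `Vp`, `w_comp`, `K_lip`); defaults are
#'   the [model_parameters()] defaults.
#' @export
fit_config <- function(n_starts = 20, bounds = default_fit_bounds(),
                       weights = c(concentration = 1, enrichment = 1),
                       max_iterations = 150, explore_iterations = 10,
                       seed = 1, rtol = 1e-5, rtol_polish = 1e-7,
                       structural = NULL) {
  if (n_starts < 1) vldl_error("n_starts must be >= 1", "vldlkin_config_error")
  for (nm in FREE_PARAMS) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      vldl_error(sprintf("bounds for %s must be finite and ordered", nm),
                 "vldlkin_config_error")
  }
  def <- model_parameters()
  structural <- modifyList(
    list(k_ge = def$k_ge, tau_sec = def$tau_sec, n_delay = def$n_delay,
         Vp = def$Vp, w_comp = def$w_comp, K_lip = def$K_lip),
    if (is.null(structural)) list() else structural)
  structure(list(n_starts = as.integer(n_starts), bounds = bounds,
                 weights = weights, max_iterations = max_iterations,
                 explore_iterations = explore_iterations,
                 seed = as.integer(seed), rtol = rtol,
                 rtol_polish = rtol_polish, structural = structural),
            class = "fit_config")
}

## ---- fast objective machinery ---------------------------------------------

# observed matrices, masks, and normalisation means for the fitted series
fit_data <- function(dataset, weights) {
  get_series <- function(nm) {
    if (nm %in% CONC_SPECIES) dataset$concentrations[[nm]]$values
    else dataset$enrichments[[nm]]$values
  }
  series <- c(FIT_CONC, FIT_ENR)
  obs <- lapply(series, get_series)
  names(obs) <- series
  mask <- lapply(obs, function(v) !is.na(v))
  norm <- lapply(obs, function(v) {
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) 1 else m
  })
  w <- setNames(ifelse(series %in% FIT_CONC, weights[["concentration"]],
                       weights[["enrichment"]]), series)
  list(series = series, obs = obs, mask = mask, norm = norm, w = w)
}

# closed-form fasting steady state as a bare state vector (fast path)
steady_vec <- function(pv, structural) {
  n <- structural$n_delay
  kch <- 24 * n / structural$tau_sec
  FCR_B1 <- pv[["k_FTR_B"]] + pv[["k_FDC_B1"]]
  FCR_T1 <- pv[["k_FTR_T"]] + pv[["k_FDC_T1"]]
  M_B1 <- pv[["P_B1"]] / FCR_B1
  M_T1 <- pv[["P_T1"]] / FCR_T1
  M_B2 <- (pv[["P_B2d"]] + pv[["k_FTR_B"]] * M_B1) / pv[["k_FCR_B2"]]
  M_T2 <- (pv[["P_T2d"]] + pv[["k_FTR_T"]] * M_T1) / pv[["k_FCR_T2"]]
  idx <- state_index(n)
  y <- numeric(2L * idx$block)
  y[idx$b1_chain] <- pv[["P_B1"]] / kch
  y[idx$b2_chain] <- pv[["P_B2d"]] / kch
  y[idx$t1_chain] <- pv[["P_T1"]] / kch
  y[idx$t2_chain] <- pv[["P_T2d"]] / kch
  y[idx$pB1] <- M_B1; y[idx$pB2] <- M_B2
  y[idx$pT1] <- M_T1; y[idx$pT2] <- M_T2
  fc_ss <- structural$K_lip / (structural$K_lip + M_T1 + W_V2 * M_T2)
  list(y = y, fc_ss = fc_ss)
}

# builds fn(pv, rtol) -> named list of predicted fitted series (or NULL on
# integration failure)
make_predictor <- function(dataset, precursor, forcing, structural) {
  sched <- dataset$schedule
  tm <- sched$times_min
  n <- structural$n_delay
  idx <- state_index(n)
  m <- idx$block
  dur <- dataset$meal$ingestion_duration_min
  template <- list(
    n_delay = n, k_ge_d = 24 * structural$k_ge,
    k_chain_d = 24 * n / structural$tau_sec,
    P_B1 = 0, P_B2d = 0, P_T1 = 0, P_T2d = 0, k_FTR_B = 0, k_FDC_B1 = 0,
    k_FCR_B2 = 0, k_FTR_T = 0, k_FDC_T1 = 0, k_FCR_T2 = 0, k_CM = 0,
    f_abs = 0, ISI = 0, I_b = forcing$I_b, w_cm = structural$w_comp,
    w_v2 = W_V2, K_lip = structural$K_lip, fc_ss = 1,
    meal_t0_d = sched$meal_time_min / 1440,
    meal_t1_d = (sched$meal_time_min + dur) / 1440,
    meal_rate = dataset$meal$tg_content * 1000 / dataset$body_weight /
      (dur / 1440),
    A_leu = precursor$leu$A, lam_leu_d = precursor$leu$lambda * 1440,
    A_gly = precursor$gly$A, lam_gly_d = precursor$gly$lambda * 1440,
    scale_leu = dataset$tracer$leucine_dose / 7,
    scale_gly = dataset$tracer$glycerol_dose / 500,
    ins_t_d = forcing$times_min / 1440, ins_y = forcing$values,
    ins_m_d = forcing$slopes * 1440)
  t_d <- tm / 1440
  Vp10 <- 10 * structural$Vp

  function(pv, rtol) {
    pl <- template
    for (nm in FREE_PARAMS) pl[[nm]] <- pv[[nm]]
    ss <- steady_vec(pv, structural)
    pl$fc_ss <- ss$fc_ss
    st <- tryCatch(.simulate_cpp(pl, ss$y, t_d, rtol, 1e-8)$states,
                   error = function(e) NULL)
    if (is.null(st)) return(NULL)
    tot <- function(i) st[, i]                     # total pool mass
    mpe <- function(i) {
      d <- st[, i]
      ifelse(d > 0, 100 * st[, m + i] / d, 0)      # labeled / total
    }
    v1 <- tot(idx$pT1) / Vp10
    v2 <- tot(idx$pT2) / Vp10
    cm <- tot(idx$cm) / Vp10
    list(V1B = tot(idx$pB1) / Vp10, V2B = tot(idx$pB2) / Vp10,
         V1TG = v1, V2TG = v2, CMTG = cm, PlasmaTG = v1 + v2 + cm,
         V1B_leu = mpe(idx$pB1), V2B_leu = mpe(idx$pB2),
         V1TG_gly = mpe(idx$pT1), V2TG_gly = mpe(idx$pT2))
  }
}

PENALTY <- 1e8

# weighted mean-normalised SSE over (a subset of) the fitted series
wsse <- function(pred, fd, subset = NULL) {
  if (is.null(pred)) return(PENALTY)
  series <- if (is.null(subset)) fd$series else subset
  s <- 0
  for (nm in series) {
    msk <- fd$mask[[nm]]
    if (!any(msk)) next
    r <- (pred[[nm]][msk] - fd$obs[[nm]][msk]) / fd$norm[[nm]]
    s <- s + fd$w[[nm]] * sum(r * r)
  }
  s
}

#' Weighted least-squares objective
#'
#' Sum over non-missing samples of squared residuals, each series normalised
#' by its observed mean (so mg/dL and MPE % series contribute comparably),
#' times the observable-class weight. A failed forward simulation returns a
#' large finite penalty (1e8) rather than an error.
#'
#' @param params a [model_parameters()] (precursor coefficients inside it
#'   are used as the forcing).
#' @param dataset a [patient_dataset()].
#' @param config a [fit_config()].
#' @return non-negative scalar.
#' @export
objective <- function(params, dataset, config = fit_config()) {
  forcing <- build_insulin_forcing(dataset$concentrations$Insulin,
                                   dataset$schedule)
  prec <- list(leu = params$precursor_leu, gly = params$precursor_gly)
  structural <- config$structural
  structural$n_delay <- params$n_delay
  for (nm in c("k_ge", "tau_sec", "Vp", "w_comp", "K_lip"))
    structural[[nm]] <- params[[nm]]
  fd <- fit_data(dataset, config$weights)
  pred <- make_predictor(dataset, prec, forcing, structural)
  pv <- unlist(params[FREE_PARAMS])
  wsse(pred(pv, config$rtol_polish), fd)
}

## ---- precursor fitting -----------------------------------------------------

# sum-of-exponentials least squares on one series; returns A, lambda, resid
fit_multiexp <- function(t, y, k) {
  ok <- !is.na(y)
  t <- t[ok]; y <- y[ok]
  if (all(y == 0))
    return(list(A = rep(0, k), lambda = rep(0.01, k), resid_norm = 0))
  design <- function(lam) exp(outer(t, lam, function(a, b) -b * a))
  # MPE(0) = sum(A) cannot exceed 100%: project runaway amplitudes back
  cap <- function(A) {
    s <- sum(A)
    if (s > 100) A * (100 / s) else A
  }
  amps <- function(lam) {
    X <- design(lam)
    a <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                  error = function(e) matrix(0, k, 1))
    cap(pmax(as.numeric(a), 0))
  }
  # decay rates above ~0.2/min are unidentifiable with the first sample at
  # 5 min (such a term vanishes before it is ever observed) and would let a
  # runaway amplitude distort the forcing on [0, 5] min
  LAM_MAX <- 0.2
  sse_lam <- function(loglam) {
    lam <- exp(loglam)
    if (any(!is.finite(lam)) || any(lam > LAM_MAX) ||
        length(unique(round(loglam, 8))) < k)
      return(1e10)
    X <- design(lam)
    sum((y - X %*% amps(lam))^2)
  }
  lam0 <- switch(k, 0.01, c(0.03, 0.003), c(0.06, 0.01, 0.002))
  lam <- if (k == 1) {
    exp(optimize(sse_lam, c(log(1e-5), log(LAM_MAX)), tol = 1e-12)$minimum)
  } else {
    o <- optim(log(lam0), sse_lam, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
    exp(o$par)
  }
  A <- amps(lam)
  # joint natural-scale polish with non-negativity
  sse_joint <- function(par) {
    A <- par[1:k]; lam <- par[(k + 1):(2 * k)]
    sum((y - design(lam) %*% A)^2) + 1e4 * max(0, sum(A) - 100)^2
  }
  oj <- tryCatch(
    optim(c(A, lam), sse_joint, method = "L-BFGS-B",
          lower = c(rep(0, k), rep(1e-6, k)),
          upper = c(rep(100, k), rep(LAM_MAX, k)),
          control = list(maxit = 400, factr = 1e3)),
    error = function(e) list(par = c(A, lam), value = sse_joint(c(A, lam))))
  A <- cap(oj$par[1:k]); lam <- oj$par[(k + 1):(2 * k)]
  ord <- order(lam, decreasing = TRUE)
  list(A = A[ord], lambda = lam[ord], resid_norm = sqrt(oj$value))
}

#' Fit the plasma precursor enrichment forcing curves
#'
#' Least-squares multi-exponential fits of the measured plasma leucine and
#' glycerol MPE, done before (and held fixed during) the kinetic fit. Two
#' terms by default; a third is kept when it improves the residual norm by
#' more than 20%. A sum of non-negative decaying exponentials is monotone
#' decreasing, so non-decaying data trigger a warning and the same
#' (monotone-constrained by construction) fit.
#'
#' @param dataset a [patient_dataset()] with `Plasma_leu` / `Plasma_gly`
#'   series (>= 4 non-missing points each).
#' @param n_terms force a term count (1-3) instead of the 2-vs-3 rule.
#' @return list with elements `leu` and `gly`, each
#'   `list(A, lambda, resid_norm)` (`lambda` in 1/min).
#' @export
fit_precursor <- function(dataset, n_terms = NULL) {
  tm <- dataset$schedule$times_min
  one <- function(pool) {
    y <- dataset$enrichments[[pool]]$values
    if (sum(!is.na(y)) < 4)
      vldl_error(sprintf("%s needs >= 4 non-missing points", pool),
                 "vldlkin_validation_error")
    yy <- y[!is.na(y)]
    if (yy[length(yy)] > yy[1] && any(yy > 0))
      warning(sprintf("%s does not decay (last > first); %s", pool,
                      "fit constrained to a monotone multi-exponential"))
    if (!is.null(n_terms)) return(fit_multiexp(tm, y, n_terms))
    f2 <- fit_multiexp(tm, y, 2)
    # only consider a third term when the 2-term residual is non-negligible
    # relative to the data scale (otherwise the 20% rule compares noise)
    if (f2$resid_norm <= 1e-5 * sqrt(sum(y^2, na.rm = TRUE))) return(f2)
    f3 <- fit_multiexp(tm, y, 3)
    if (f3$resid_norm < 0.8 * f2$resid_norm) f3 else f2
  }
  list(leu = one("Plasma_leu"), gly = one("Plasma_gly"))
}

## ---- multi-start fit -------------------------------------------------------

to_opt <- function(pv) {
  out <- pv
  out[LOG_PARAMS] <- log(pmax(pv[LOG_PARAMS], 1e-12))
  out
}
from_opt <- function(th) {
  out <- th
  out[LOG_PARAMS] <- exp(th[LOG_PARAMS])
  out
}

opt_bounds <- function(bounds) {
  lo <- vapply(FREE_PARAMS, function(nm) bounds[[nm]][1], 0)
  hi <- vapply(FREE_PARAMS, function(nm) bounds[[nm]][2], 0)
  list(lo = to_opt(pmax(lo, setNames(ifelse(FREE_PARAMS %in% LOG_PARAMS,
                                            1e-6, 0), FREE_PARAMS))),
       hi = to_opt(hi))
}

# seeded space-filling starts in the transformed space: randomised Halton
# sequence (random shift per dimension), so start sets are nested in n and
# the best reachable objective is non-increasing in n_starts
halton_1d <- function(i, base) {
  f <- 1
  r <- 0
  while (any(i > 0)) {
    f <- f / base
    r <- r + f * (i %% base)
    i <- i %/% base
  }
  r
}

halton_starts <- function(n, lo, hi) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41)
  d <- length(lo)
  shift <- runif(d)
  u <- vapply(seq_len(d), function(j)
    (halton_1d(seq_len(n), bases[j]) + shift[j]) %% 1, numeric(n))
  if (n == 1) u <- matrix(u, nrow = 1)
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Fit one patient-condition dataset
#'
#' Seeded multi-start bound-constrained weighted least squares. Each
#' space-filling start is explored with a short local search (TG/CM block
#' against the TG observables, then apoB block against the apoB
#' observables); the best candidates get a full-objective joint polish.
#' The insulin effect is declared detected when the estimated ISI exceeds
#' 0.01 and removing the insulin multiplier (ISI = 0, all else equal)
#' worsens the objective by more than 2%.
#'
#' @param dataset a [patient_dataset()].
#' @param config a [fit_config()].
#' @param precursor optional precomputed [fit_precursor()] result.
#' @return object of class `fit_result`: `params` (best-fit
#'   [model_parameters()]), `objective`, `residuals` (per-series,
#'   mean-normalised), `converged`, `n_starts`, `start_objectives`,
#'   `n_within_1pct` (polished candidates within 1% of the best objective),
#'   `insulin_effect_detected`, `isi_zero_objective`.
#' @export
fit_patient <- function(dataset, config = fit_config(), precursor = NULL) {
  set.seed(config$seed)
  if (is.null(precursor)) precursor <- fit_precursor(dataset)

  fix_isi <- FALSE
  forcing <- tryCatch(
    build_insulin_forcing(dataset$concentrations$Insulin, dataset$schedule),
    vldlkin_validation_error = function(e) NULL)
  if (is.null(forcing)) {
    # all-missing insulin: flat forcing, ISI pinned to 0
    fix_isi <- TRUE
    ib <- if (!is.na(dataset$fasting_insulin)) dataset$fasting_insulin else 10
    forcing <- structure(list(I_b = ib, times_min = c(0, 1440),
                              values = c(ib, ib), slopes = c(0, 0),
                              fun = function(t) rep(ib, length(t))),
                         class = "insulin_forcing")
  }

  fd <- fit_data(dataset, config$weights)
  predict_at <- make_predictor(dataset, precursor, forcing,
                               config$structural)
  ob <- opt_bounds(config$bounds)
  if (fix_isi) ob$lo["ISI"] <- ob$hi["ISI"] <- 0

  full_obj <- function(th, rtol) wsse(predict_at(from_opt(th), rtol), fd)
  sub_obj <- function(th_sub, th_full, sel, series, rtol) {
    th_full[sel] <- th_sub
    wsse(predict_at(from_opt(th_full), rtol), fd, subset = series)
  }
  run_block <- function(th, sel, series, maxit, rtol) {
    o <- tryCatch(
      optim(th[sel], sub_obj, th_full = th, sel = sel, series = series,
            rtol = rtol, method = "L-BFGS-B",
            lower = ob$lo[sel], upper = ob$hi[sel],
            control = list(maxit = maxit)),
      error = function(e) list(par = th[sel], value = PENALTY,
                               convergence = 99))
    th[sel] <- o$par
    list(th = th, value = o$value)
  }

  starts <- halton_starts(config$n_starts, ob$lo, ob$hi)
  colnames(starts) <- FREE_PARAMS

  # stage A: TG/CM block per start
  explored <- lapply(seq_len(config$n_starts), function(i) {
    run_block(starts[i, ], TG_BLOCK, TG_SERIES,
              config$explore_iterations, config$rtol)
  })
  tg_vals <- vapply(explored, `[[`, 0, "value")
  top <- order(tg_vals)[seq_len(min(5, length(explored)))]

  # stage B: apoB block for the leading TG candidates, then joint polish
  candidates <- lapply(top, function(i) {
    rb <- run_block(explored[[i]]$th, APOB_BLOCK, APOB_SERIES,
                    2 * config$explore_iterations, config$rtol)
    rb$th
  })
  # rank candidates by full objective before spending polish effort
  cand_vals <- vapply(candidates, function(th)
    full_obj(th, config$rtol), 0)
  candidates <- candidates[order(cand_vals)]
  polished <- lapply(seq_along(candidates), function(j) {
    maxit <- if (j <= 2) config$max_iterations else
      max(15, config$max_iterations %/% 5)
    tryCatch(
      optim(candidates[[j]], full_obj, rtol = config$rtol_polish,
            method = "L-BFGS-B", lower = ob$lo, upper = ob$hi,
            control = list(maxit = maxit, factr = 1e4)),
      error = function(e) list(par = candidates[[j]], value = PENALTY,
                               convergence = 99))
  })
  vals <- vapply(polished, `[[`, 0, "value")
  best <- polished[[which.min(vals)]]
  if (all(vals >= PENALTY))
    vldl_error(paste0("all starts failed; stage-A objectives: ",
                      paste(signif(tg_vals, 4), collapse = " ")),
               "vldlkin_estimation_error")

  pv <- from_opt(best$par)
  params <- do.call(model_parameters, c(
    as.list(pv), config$structural,
    list(precursor_leu = precursor$leu[c("A", "lambda")],
         precursor_gly = precursor$gly[c("A", "lambda")])))

  pred <- predict_at(pv, config$rtol_polish)
  residuals <- lapply(fd$series, function(nm) {
    r <- (pred[[nm]] - fd$obs[[nm]]) / fd$norm[[nm]]
    r[!fd$mask[[nm]]] <- NA
    r
  })
  names(residuals) <- fd$series

  pv0 <- pv
  pv0["ISI"] <- 0
  obj0 <- wsse(predict_at(pv0, config$rtol_polish), fd)
  detected <- !fix_isi && pv[["ISI"]] > 0.01 &&
    obj0 > 1.02 * best$value

  structure(list(
    params = params, objective = best$value, residuals = residuals,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    n_starts = config$n_starts, start_objectives = tg_vals,
    n_within_1pct = sum(vals <= 1.01 * min(vals)),
    insulin_effect_detected = detected, isi_zero_objective = obj0,
    seed = config$seed), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective %.4g (%d starts, %d within 1%%), %s\n",
              x$objective, x$n_starts, x$n_within_1pct,
              if (x$insulin_effect_detected) "insulin effect detected"
              else "no insulin effect"))
  print(x$params)
  invisible(x)
}

#' Approximate per-parameter uncertainty from objective curvature
#'
#' Finite-difference Hessian of the objective at the optimum on the
#' transformed scale, converted to standard errors via the usual
#' least-squares covariance `2 s^2 H^{-1}`. Approximate by construction (no
#' profile likelihood); flagged as such.
#'
#' @param fit a [fit_patient()] result.
#' @param dataset the fitted [patient_dataset()].
#' @param config the [fit_config()] used.
#' @return data.frame of parameter, estimate, approximate SE (natural
#'   scale, via the delta method for log-parameters).
#' @export
fit_uncertainty <- function(fit, dataset, config = fit_config()) {
  forcing <- build_insulin_forcing(dataset$concentrations$Insulin,
                                   dataset$schedule)
  prec <- list(leu = fit$params$precursor_leu, gly = fit$params$precursor_gly)
  fd <- fit_data(dataset, config$weights)
  predict_at <- make_predictor(dataset, prec, forcing, config$structural)
  th <- to_opt(unlist(fit$params[FREE_PARAMS]))
  f <- function(t) wsse(predict_at(from_opt(t), config$rtol_polish), fd)
  H <- numDeriv::hessian(f, th)
  nobs <- sum(vapply(fd$mask, sum, 0L))
  s2 <- fit$objective / max(1, nobs - length(th))
  cv <- tryCatch(2 * s2 * solve(H), error = function(e)
    matrix(NA_real_, length(th), length(th)))
  se_t <- sqrt(pmax(diag(cv), 0))
  est <- unlist(fit$params[FREE_PARAMS])
  se <- ifelse(FREE_PARAMS %in% LOG_PARAMS, est * se_t, se_t)
  data.frame(parameter = FREE_PARAMS, estimate = unname(est),
             se_approx = unname(se))
}
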