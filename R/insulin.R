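## Insulin module: the measured plasma insulin excursion is an exogenous
## forcing. The interpolant is shape-preserving monotone cubic Hermite
## (Fritsch-Carlson slopes) with constant extrapolation outside the samples.

# Fritsch-Carlson monotone Hermite slopes for knots (x, y)
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  d <- diff(y) / h
  m <- numeric(n)
  if (n == 2) return(c(d, d))
  m[1] <- d[1]
  m[n] <- d[n - 1]
  for (i in 2:(n - 1)) {
    if (d[i - 1] * d[i] <= 0) m[i] <- 0
    else {
      w1 <- 2 * h[i] + h[i - 1]
      w2 <- h[i] + 2 * h[i - 1]
      m[i] <- (w1 + w2) / (w1 / d[i - 1] + w2 / d[i])
    }
  }
  # limit endpoint slopes to preserve monotonicity
  for (i in c(1, n)) {
    di <- if (i == 1) d[1] else d[n - 1]
    if (di == 0) m[i] <- 0
    else if (sign(m[i]) != sign(di)) m[i] <- 0
    else if (abs(m[i]) > 3 * abs(di)) m[i] <- 3 * di
  }
  m
}

eval_pchip <- function(x, y, m, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    n <- length(x)
    if (q >= x[n]) return(y[n])
    i <- findInterval(q, x)
    h <- x[i + 1] - x[i]
    s <- (q - x[i]) / h
    (2 * s^3 - 3 * s^2 + 1) * y[i] + (s^3 - 2 * s^2 + s) * h * m[i] +
      (-2 * s^3 + 3 * s^2) * y[i + 1] + (s^3 - s^2) * h * m[i + 1]
  }, 0)
}

#' Build the insulin forcing from a measured insulin series
#'
#' The basal level `I_b` is the mean of the pre-meal samples; between samples
#' the forcing is a shape-preserving monotone cubic interpolant, and beyond
#' the last sample it is held constant.
#'
#' @param insulin_series a [concentration_series()] with species `Insulin`.
#' @param schedule the study [sampling_schedule()].
#' @return object of class `insulin_forcing`: fields `I_b` (mU/L), knot
#'   vectors, and `fun(t_min)` evaluating I(t) in mU/L.
#' @export
build_insulin_forcing <- function(insulin_series, schedule) {
  stopifnot(inherits(insulin_series, "concentration_series"),
            insulin_series$species == "Insulin")
  tm <- schedule$times_min
  v <- insulin_series$values
  ok <- !is.na(v)
  if (!any(ok))
    vldl_error(paste("insulin series is entirely missing; fix ISI at 0",
                     "instead of building a forcing"),
               "vldlkin_validation_error")
  pre <- ok & tm <= schedule$meal_time_min
  if (sum(pre) < 2)
    vldl_error("need >= 2 non-missing pre-meal insulin samples",
               "vldlkin_validation_error")
  I_b <- mean(v[pre])
  x <- tm[ok]
  y <- v[ok]
  m <- pchip_slopes(x, y)
  f <- function(t_min) eval_pchip(x, y, m, t_min)
  structure(list(I_b = I_b, times_min = x, values = y, slopes = m, fun = f),
            class = "insulin_forcing")
}

#' Insulin multiplier of LPL-mediated lipolysis fluxes
#'
#' `phi = 1 + ISI * max(0, (I - I_b)/I_b)`: the lipolysis pathway responds
#' linearly to the fractional rise of insulin above baseline and is never
#' suppressed below its basal capacity (`phi >= 1`).
#'
#' @param I plasma insulin, mU/L (vectorized).
#' @param I_b basal insulin, mU/L (> 0).
#' @param ISI lipoprotein-lipolysis insulin sensitivity index (>= 0).
#' @return dimensionless multiplier(s) >= 1.
#' @export
lipolysis_multiplier <- function(I, I_b, ISI) {
  if (I_b <= 0)
    vldl_error("basal insulin must be > 0", "vldlkin_domain_error")
  if (ISI < 0)
    vldl_error("ISI must be >= 0", "vldlkin_domain_error")
  1 + ISI * pmax(0, (I - I_b) / I_b)
}
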