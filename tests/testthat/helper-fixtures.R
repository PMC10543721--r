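# Shared fixtures, all built in code.

# a plausible postprandial insulin excursion on the study grid
test_insulin_values <- function() {
  c(12, 12, 12, 12, 12, 12, 12, 12, 40, 70, 60, 35, 20, 14, 12, 12)
}

test_forcing <- function(sched = sampling_schedule()) {
  build_insulin_forcing(
    concentration_series("Insulin", test_insulin_values()), sched)
}

# one deterministic small dataset + its truth, cached per session
local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

noiseless_config <- function(n = 1, seed = 11)
  cohort_config(n_patients = n, seed = seed,
                noise_cv = c(concentration = 0, enrichment = 0))

noiseless_patient <- function(cond = "pre")
  cached(paste0("noiseless_", cond),
         generate_patient(cond, noiseless_config(), 1))

# small/cheap estimation config for unit tests (full-size runs live in
# test-acceptance.R)
cheap_fit_config <- function(n_starts = 8, seed = 5)
  fit_config(n_starts = n_starts, seed = seed, explore_iterations = 8,
             max_iterations = 60, rtol_polish = 1e-6)

free_param_names <- function()
  c("P_B1", "P_B2d", "P_T1", "P_T2d", "k_FTR_B", "k_FDC_B1", "k_FCR_B2",
    "k_FTR_T", "k_FDC_T1", "k_FCR_T2", "k_CM", "f_abs", "ISI")

rel_err <- function(est, tru) abs(est - tru) / pmax(abs(tru), 1e-12)
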