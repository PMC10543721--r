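---
title: "Modelling postprandial VLDL apoB and TG kinetics from dual-tracer mixed-meal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postprandial VLDL apoB and TG kinetics from dual-tracer mixed-meal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vldlkin)
```

## The problem

Triglyceride-rich lipoprotein metabolism is usually studied with
stable-isotope tracers under fasting steady-state conditions. Humans,
however, spend most of the day postprandially, and the dyslipidemia of
obesity is most pronounced after meals, when intestinally secreted
chylomicrons (CM) flood the shared lipoprotein-lipase (LPL) lipolysis
machinery and compete with hepatically secreted VLDL. `vldlkin` implements
a physiologically based compartmental model of this non-steady state: a
dual tracer bolus (deuterated leucine labelling apoB, deuterated glycerol
labelling TG) is given at time 0, a liquid mixed meal at 120 min, and
plasma concentrations plus tracer enrichments (molar percent excess, MPE)
of VLDL~1~ and VLDL~2~ apoB and TG are observed on a fixed grid out to 24 h.
Fitting the model per subject yields production rates, fractional transfer
(FTR), direct catabolic (FDC) and catabolic (FCR) rates, the intestinal
absorption fraction, CM TG clearance, and an insulin sensitivity index of
the lipolysis pathway (ISI).

## Model structure

The ODE system has five modules:

* **Gastrointestinal** — meal TG enters the stomach as a zero-order boxcar
  over the ingestion duration (10 min before surgery, 30 min at follow-up),
  empties into the gut lumen at first order (`k_ge`, default 1.2/h, a
  liquid-meal scale value), and a fraction `f_abs` is absorbed into a CM
  secretion-delay chain; the remainder is lost. The CM pool is cleared at
  `k_CM`.
* **Liver** — VLDL~1~ and VLDL~2~ apoB and TG are produced at constant rates
  (`P_B1`, `P_B2d`, `P_T1`, `P_T2d`, mg/kg/d) through Erlang delay chains
  (`n_delay = 3` sub-compartments, total delay `tau_sec = 0.75` h) that
  reproduce the ~1 h lag before labelled material appears in plasma.
* **Plasma** — VLDL~1~ pools lose material by LPL-mediated delipidation to
  VLDL~2~ (`k_FTR_B`, `k_FTR_T`) and by direct removal (`k_FDC_B1`,
  `k_FDC_T1`); VLDL~2~ pools are cleared at `k_FCR_B2`, `k_FCR_T2`. The
  VLDL~1~ FCRs are identities, `FCR = FTR + FDC`, never free parameters.
* **Tracer** — the plasma precursor enrichment after the bolus is an
  exogenous forcing `MPE(t) = sum A_i exp(-lambda_i t)` fitted per subject
  *before* the kinetic fit and held fixed (standard practice in apoB
  turnover modelling: it decouples precursor kinetics from lipoprotein
  parameters). The labelled state block is a *sub-mass* of the total pool
  (production `P * MPE(t)/100` against total production `P`), the massless
  tracer idealization: the labelled subsystem is exactly linear in dose and
  labelled mass can never exceed pool mass. Meal TG is treated as
  unlabelled.
* **Insulin** — measured plasma insulin, interpolated shape-preservingly
  (monotone cubic Hermite), is an exogenous forcing, never a model state.
  Every LPL-mediated flux (CM clearance, VLDL1→VLDL2 transfer, TG
  catabolism) is multiplied by `phi = 1 + ISI * max(0, (I - I_b)/I_b)`,
  where `I_b` is the pre-meal mean. The multiplier is clamped below at 1:
  the ISI is defined on the fractional *increase* of insulin over baseline.

### Competition for lipolysis

All TG-rich particles compete for shared LPL capacity. The raw saturation
factor is

`fc = K_lip / (K_lip + w_CM * TG_CM + TG_V1 + 0.5 * TG_V2)`

with size-ordered weights (`w_CM = w_comp = 3` by default, VLDL~1~ weight
1, VLDL~2~ weight 0.5) and half-saturation mass `K_lip = 300` mg/kg.
Inside the simulator the factor is **normalised to its fasting value**, so
lipolytic fluxes are scaled by `fc(t)/fc(fasting)`. This choice makes the
estimated fractional rates fasting-referenced, which in turn makes the
fasting steady state an exact linear flux balance (`M = P/FCR` etc.) — the
alternative (raw factor everywhere) would make the fasting state a
nonlinear fixed point and the printed rate constants condition-dependent.
The qualitative behaviour is identical: postprandial CM influx depresses
VLDL lipolysis and delipidation, producing the characteristic VLDL
accumulation before surgery.

### What is deliberately absent

Insulin-mediated suppression of hepatic apoB production is *not* in the
model (it proved undetectable from this sampling design and was dropped
from the final model the package mirrors). There is no apoB48 particle
bookkeeping, no FFA re-esterification, no cholesterol.

## Parameter estimation

Per subject-condition the 13 free parameters are estimated by
bound-constrained weighted least squares. Each observed series contributes
squared residuals normalised by the series' observed mean (so mg/dL
concentrations and % enrichments are commensurate), class weights default
to 1. Missing samples are masked, never imputed. The optimiser is
multi-start (default 20 seeded randomised-Halton starts; the start set is
nested in `n_starts`, so more starts can only improve the best objective):
each start gets a short bound-constrained local search of the TG/CM block
against the TG observables (apoB pools do not feed back on TG dynamics, so
this restriction is exact), the leading candidates get an apoB-block
search, and the best candidates a joint polish on the full objective on
the log scale for positive parameters. Bounds are generous envelopes:
production to 2000 mg/kg/d (TG production in severe obesity runs to
~1 mg/kg/min), fractional rates to 100 pools/d, ISI in [0, 2], `f_abs` in
[0.2, 1].

The **insulin effect is declared detected** when the estimated ISI exceeds
0.01 *and* removing the insulin multiplier (ISI = 0, all else fixed)
worsens the objective by more than 2%. This operationalises the clinical
observation that in some pre-surgery subjects no insulin effect on
lipolysis is detectable; the threshold pair is this package's own rule.

Precursor curves use 2 exponential terms by default, 3 only when the
residual norm improves by more than 20% *and* the 2-term residual is
non-negligible; decay rates are capped at 0.2/min because a faster term
has decayed below visibility before the first sample at 5 min and its
amplitude would be unidentifiable (a runaway fast term distorts the
forcing on [0, 5] min and biases every downstream parameter).

### Numerical choices

The ODE system (44 states at `n_delay = 3`) is integrated with an adaptive
Dormand–Prince 5(4) method compiled in C++ (`rtol` 1e-8, `atol` 1e-10 for
reported simulations; 1e-5/1e-6 inside the optimiser where the objective
tolerates it). Integration is segmented at the meal boxcar edges so the
discontinuity never sits inside a step. Failed integrations inside the
objective return a large finite penalty (1e8) instead of erroring, keeping
line searches alive; negative states beyond 1e-6 of scale abort loudly
rather than being clipped.

## The synthetic cohort: a stated world

`generate_cohort()` creates paired pre/post virtual patients on the exact
study protocol. Its defaults *are* the package's stated world, chosen once
for physiological plausibility, and the directional pre-to-post shifts
mirror the clinical findings they emulate: lower VLDL~1~ apoB and TG
production after surgery, unchanged VLDL~2~ apoB direct production, higher
TG catabolic and transfer rates, ~70% higher CM TG clearance, lower
intestinal absorption (0.75–0.95 → 0.5–0.75), and higher lipolysis ISI
(uniform 0–0.4 → 0.1–0.7; ISI is drawn uniformly because its presurgery
range includes 0, all other parameters log-uniformly). Insulin is an
exogenous template (basal 10–20 mU/L pre, 4–9 post; peak 3–5× / 5–8×
basal at 30–60 min after meal start, back to basal by ~4 h), shared
un-noised between truth and observation, exactly as the estimation stage
treats measured insulin. Measurement noise is multiplicative lognormal
with mean 1 (CV 5% for concentrations, 8% for enrichments, the scale of
the reported assay CVs); MPE is clipped to [0, 100] after noising. A
patient-level latent "insulin resistance" quantile correlates the
production draws with basal insulin so that HOMA-IR–production
correlation panels are non-degenerate; no other covariance structure of
the real cohort is emulated.

What a green synthetic test establishes: that the pipeline recovers known
parameters from data *generated by its own forward model* under realistic
noise, grids and protocol asymmetries. What it cannot establish: model
mis-specification against real biology, assay artefacts, or the clinical
cohort's printed values — those live in the deposited clinical dataset,
which is not redistributable here.

## Derived quantities and statistics

Postprandial AUCs are plain trapezoids over the observed 2–10 h samples
(no baseline subtraction), peak times are grid argmaxima (earliest on
ties) on the observed series, not the fitted curves; TG:apoB AUC ratios
proxy particle TG load. Clamp indices use the Steele equations (steady
`Ra = F/TTR`; non-steady with pool-fraction × volume 0.104 L/kg for
glucose, 0.150 L/kg for glycerol, plateau = last 30 min of each step) and
are normalised by the step's fractional insulin rise. Cohort comparisons
are one-tailed paired t tests (direction defaulting to the observed mean
change, configurable per variable), correlations are Pearson with the
exact t-transform p; no multiple-testing correction is applied, matching
the source analysis convention.

## Known limitations

* `tau_sec`, `n_delay`, `k_ge`, `Vp`, `w_comp` and `K_lip` are fixed
  structural constants during estimation; profile identifiability of the
  competition constants from a single meal is poor, so freeing them is not
  the default.
* The curvature-based parameter uncertainty (`fit_uncertainty()`) is a
  local quadratic approximation, not a profile likelihood.
* ISI is weakly identified when the true value is near 0 (relative errors
  blow up even though absolute errors stay small); cohort medians are the
  honest summary.
* Peak times are grid-resolution-limited (the grid spacing around the peak
  is 60 min).
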