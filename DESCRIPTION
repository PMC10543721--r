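Package: vldlkin
Title: Postprandial VLDL ApoB and Triglyceride Kinetics from Stable-Isotope
    Tracer Data
Version: 0.1.0
Authors@R:
    person("vldlkin", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physiologically based compartmental modelling of postprandial
    VLDL1/VLDL2 apolipoprotein B and triglyceride kinetics from dual
    stable-isotope (leucine/glycerol) tracer mixed-meal studies. Provides a
    deterministic ODE forward model with gastrointestinal, plasma, liver,
    tracer and insulin modules; bound-constrained multi-start nonlinear
    least-squares parameter estimation; a lipoprotein-lipolysis insulin
    sensitivity index; derived kinetic summaries (production rates, FCR, FTR,
    FDC, AUCs, peak times, TG:apoB ratios); hyperinsulinemic-euglycemic clamp
    flux calculations (Steele equations) and insulin-sensitivity indices;
    paired cohort statistics; and a fully reproducible synthetic-cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    numDeriv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
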