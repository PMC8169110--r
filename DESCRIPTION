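Package: tumorpkpd
Title: Mechanistic PK/PD Modelling of Peptide-Targeted Tumor Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic pharmacokinetic-pharmacodynamic modelling of breast
    tumor growth under targeted peptide therapy and ligand-directed suicide
    gene therapy with ganciclovir. Tumor volume follows logistic growth
    opposed by a Michaelis-Menten peptide kill term and a kill term linear in
    plasma ganciclovir, coupled to one-compartment pharmacokinetics with
    impulsive intravenous/intraperitoneal dosing or constant-rate infusion.
    Provides closed-form pharmacokinetic solutions, sequential nonlinear
    least-squares calibration against longitudinal cohort measurements, a
    synthetic-cohort generator for pipeline validation, dissociation-constant
    sensitivity analysis, and simulation of a bolus-versus-infusion trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
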