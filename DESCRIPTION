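Package: pkpdco
Title: Population PK/PD and Clinical-Outcome Modelling of Inhaled Budesonide/Formoterol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and population estimation for the combined
    pharmacokinetic (PK), pharmacodynamic (PD) and clinical-outcome (CO) model of
    inhaled budesonide/formoterol therapy in moderate asthma. Inhaled doses are
    split between a lung and a gut absorption depot; plasma kinetics follow
    linear one-compartment (formoterol) and two-compartment (budesonide) models;
    lung concentrations drive indirect-response (turnover) models for sputum
    eosinophil cationic protein and FEV1; and a disease-progression equation maps
    biomarker changes onto the Asthma Control Test score. The package provides a
    FOCE-I-style approximate marginal-likelihood estimator with likelihood-ratio
    testing and stepwise covariate modelling, clinical-trial simulation of dosing
    regimens with control-status classification, model diagnostics (visual
    predictive check, nonparametric bootstrap, noncompartmental analysis), and a
    generator of trial-shaped synthetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
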