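Package: tdprisk
Title: In Silico Torsade-de-Pointes Risk Classification from Ion-Channel
    Block Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for proarrhythmic (Torsade de Pointes)
    risk assessment of drugs in the CiPA paradigm. Per-channel
    dose-inhibition measurements are summarised as Hill curves with
    bootstrap uncertainty clouds, drug block is applied multiplicatively
    to the conductances of a paced ventricular-myocyte model, twelve in
    silico biomarkers (action-potential, calcium-transient and ionic
    charge features such as APD90, CaD50, qNet and qInward) are extracted
    from the worst repolarising beat and averaged over four concentration
    multiples of Cmax, and a single-feature proportional-odds ordinal
    regression classifies drugs into low, intermediate and high TdP risk.
    Classifier performance is evaluated by a repeated one-sample-per-drug
    bootstrap test procedure (per-class ROC AUC, likelihood ratios,
    accuracy, F1). A fast analytic surrogate myocyte model with
    closed-form feature values makes every stage testable without
    external data or long simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
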