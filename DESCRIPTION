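Package: halopbpk
Title: Whole-Body Parent-Metabolite PBPK Model of Haloperidol and Reduced Haloperidol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) modelling of
    haloperidol and its carbonyl-reduction metabolite, reduced haloperidol.
    Implements a whole-body perfusion-limited compartment model with
    Rodgers-Rowland tissue partitioning, compartmental gastro-intestinal
    absorption, saturable hepatic metabolism parameterised from in vitro
    enzyme kinetics (CYP3A4, CBR1, UGT1A4/1A9/2B7) with in-vitro-to-in-vivo
    scaling, glomerular-filtration renal elimination, and molar
    parent-to-metabolite cycling.  Includes virtual-population simulation,
    a static CYP3A4-induction drug-drug-interaction scenario for rifampicin
    co-treatment, a tuberculosis plasma-protein-binding adjustment,
    non-compartmental analysis, and model-qualification statistics
    (predicted/observed ratio, prediction error, mean fold error, RMSE,
    two-fold check, visual-predictive-check percentile bands).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
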