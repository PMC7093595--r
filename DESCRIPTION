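Package: mtanc
Title: Population PK/PD Modelling of Neutrophil Dynamics During ALL
    Maintenance Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-mechanistic pharmacokinetic/pharmacodynamic modelling of
    absolute neutrophil counts (ANC) in children receiving oral
    6-mercaptopurine maintenance chemotherapy for acute lymphoblastic
    leukemia.  Couples a linear three-compartment 6MP to 6-thioguanine
    nucleotide model with a transit-compartment (Friberg-type)
    myelosuppression model, estimates population parameters by first-order
    conditional estimation with eta-epsilon interaction (FOCE-I), and
    provides a virtual-cohort generator with closed-loop dose titration,
    CRP-based measurement exclusion, chronological cross-validation,
    visual predictive checks, and an in-silico comparison of constant
    mg-per-square-metre dosing protocols.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
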