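Package: decolcea
Title: Cost-Effectiveness of Universal and Targeted Chlorhexidine
    Decolonization for Hospital-Onset Bacteremia Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing universal decolonization,
    targeted decolonization of patients with medical devices, and standard
    of care for preventing hospital-onset bacteremia and fungemia (HOB) in
    non-ICU inpatients. Evaluates an eight-stratum decision tree (device,
    MRSA history, surgical admission) with treatment effects expressed as
    hazard rate ratios, computes expected HOB events and upstream/downstream
    costs per 1000 admissions from payer and hospital perspectives, ranks
    strategies by dominance and incremental cost-effectiveness ratios,
    and propagates parameter uncertainty through probabilistic sensitivity
    analysis. Includes one-way and multi-way deterministic sensitivity
    analyses, willingness-to-pay threshold analyses, and an independent
    patient-level microsimulation used to validate the cohort expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
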