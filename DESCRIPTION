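Package: pnpcea
Title: Decision-Tree Cost-Utility Model for Capsaicin 8% Patch versus
    Pregabalin in Peripheral Neuropathic Pain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree cost-utility model comparing a single
    application of capsaicin 8% patch with dose-optimized pregabalin for
    peripheral neuropathic pain from a health-service payer perspective.
    Patients are classified at an 8-week assessment as responders,
    non-responders, or discontinuers due to intolerable adverse events;
    non-responders and discontinuers switch to last-line therapy.
    Utilities follow piecewise-linear trajectories integrated exactly and
    discounted by model year. The package provides the deterministic
    cohort engine, a named scenario suite (including waning of effect and
    topical anesthesia), structural horizon sweeps, one-way deterministic
    sensitivity analysis with tornado ranking and threshold solving,
    seeded probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a patient-level microsimulation used as an
    independent validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
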