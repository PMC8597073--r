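Package: fontanlist
Title: Optimal Transplant Listing Windows for Failing Fontan Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision support for timing the heart-transplant listing of
    patients with a failing Fontan circulation, framed as a real-options
    optimal-stopping problem. A bedside comorbidity checklist is scored into
    a net signal count, Bayesian belief updating converts the count into a
    probability of a good post-transplant outcome, and closed-form upper and
    lower belief thresholds delimit three regions: too well to list, list
    now, and too unwell to remain listed. The package provides the threshold
    calculator and three-way decision rule, the regional value functions and
    their boundary-condition diagnostics, an independent free-boundary
    lattice solver that validates the closed forms numerically, a seeded
    Monte Carlo trajectory simulator for policy evaluation, parameter
    sensitivity sweeps, signal-quality estimation from historical outcome
    records, and checklist file I/O with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
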