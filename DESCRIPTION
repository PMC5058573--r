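Package: clinicflow
Title: Discrete-Event Simulation of Mixed-Registration Outpatient Clinics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic, seedable discrete-event simulator of an
    orthopedic outpatient clinic with mixed registration (walk-in and
    scheduled patients), including the clinic's queue disciplines
    (walk-in/scheduled alternation, priority for special patients,
    postponement of late arrivals), an examination re-entry loop, and
    registration and pharmacy stations. Provides nonhomogeneous Poisson
    arrival generation, per-session configuration and calibration,
    terminating-simulation replication statistics with Student-t
    confidence intervals, paired t-test comparison of waiting times
    before and after an operational change, and a per-session policy
    search over alternative queue disciplines under common random
    numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
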