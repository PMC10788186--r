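Package: ctmismatch
Title: CT Hypoperfusion-Hypodensity Mismatch and Automated Perfusion
    Mismatch for Thrombolysis Eligibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments ischemic core and penumbra from co-registered CT
    perfusion parameter maps (CBV, CBF, MTT, TTD, Tmax), decides the CT
    hypoperfusion-hypodensity mismatch -- a net-water-uptake "tissue
    clock" that flags stroke patients still within the thrombolysis
    window -- and the EXTEND-style automated perfusion mismatch, and
    evaluates both binary classifiers against eligibility labels with
    exact Clopper-Pearson diagnostic-accuracy statistics. Ships a
    digital head-phantom generator (NCCT plus perfusion maps with
    ground-truth lesion geometry and onset times) and a cohort
    simulator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
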