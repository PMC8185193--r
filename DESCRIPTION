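Package: MenoRad
Title: Ovarian Dose, Follicle Survival and Premature Menopause Modelling
    for Lymphoma Radiotherapy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the gonadal impact of radiotherapy
    target-volume choice in Hodgkin lymphoma. Reads and manipulates
    dose-volume histograms (DVHs) from planning-system exports, applies the
    Wallace ovarian follicle survival function bin-wise over the combined
    both-ovaries DVH, converts the surviving non-growing-follicle (NGF)
    fraction into a predicted time to premature menopause through the Hansen
    NGF-age model and its closed-form inverse, and compares paired
    involved-field (IFRT) versus involved-site (ISRT) plans across a cohort
    with the exact sign test. A companion module fits the weighted
    least-squares regression of log-transformed FSH and LH on age, sex,
    chemotherapy regimen and radiotherapy field location. Seeded synthetic
    cohort generators emulate the paired-plan and hormone data so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
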