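Package: radcomp
Title: Radiotherapy Plan Evaluation with DVH Metrics and Radiobiological Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and comparing external-beam radiotherapy
    treatment plans from dose-volume histogram (DVH) data. Implements the
    standard dosimetric plan-quality indices (homogeneity index, conformity
    index, Dx%, V_RI, Dmin/Dmax/Dmean), fractionation-corrected radiobiological
    endpoints (EQD2-type dose conversion under the linear-quadratic model,
    Niemierko generalized equivalent uniform dose, Poisson linear-quadratic
    tumor control probability, and Lyman-Kutcher-Burman normal tissue
    complication probability), and two-arm cohort comparison by independent
    two-sample t-tests. Includes a seedable synthetic-cohort generator that
    emulates per-patient, per-structure DVHs for conventionally fractionated
    (50 Gy / 25 fractions) and hypofractionated (42.56 Gy / 16 fractions)
    whole-breast arms, a plain-text CSV DVH exchange format, and an
    end-to-end comparison pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
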