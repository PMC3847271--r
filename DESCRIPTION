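Package: livesaved
Title: Deterministic Lives-Saved Projection of Health Intervention Scale-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, linear intervention-impact engine for maternal,
    neonatal and child health programs. Given a base-year country health
    profile (mortality rates, proportional cause-of-death structures by age
    band, baseline intervention coverage, annual live births) and one or more
    coverage scale-up scenarios, the package projects cause-specific deaths by
    age band and year, computes lives saved against a constant-coverage
    counterfactual, and attributes lives saved to individual interventions
    using preventive-first, proportional-within-block rules. Combined impacts
    are applied multiplicatively to residual deaths so that simultaneous
    scale-up of several interventions on the same cause is never double
    counted, and survivors of each age band cascade into the next band's
    at-risk cohort. Includes a deterministic synthetic-profile generator, a
    YAML/JSON scenario format, tidy CSV outputs and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
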