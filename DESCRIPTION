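Package: mortlink
Title: Multi-Stage Deterministic Linkage of Dual Mortality Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic, multi-variable, multi-stage linkage of two
    suicide and undetermined-intent mortality registries within state-year
    strata: a gold-standard Veteran registry (MDR-like) and a noisier
    violent-death surveillance registry (NVDRS-like).  Implements the
    three-stage, seven-pass linkage with concatenated match keys and
    progressively relaxed criteria, a deterministic duplicate-resolution
    cascade (multiple-cause-of-death containment, relaxed-field review,
    military-history indicator), linkage-success evaluation (match rates
    overall, by stage tier and by state-year; complete state-year
    filtering; concordance diagnostics; missingness profiling), and a
    validity assessment of the surveillance registry's military-history
    indicator (sensitivity, specificity, accuracy, PPV, NPV with 95%
    confidence intervals, stratified by manner of death, sex and age).  A
    synthetic dual-registry generator with ground-truth links makes every
    stage verifiable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
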