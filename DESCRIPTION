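Package: bpvalidate
Title: Accuracy Evaluation of Blood Pressure Devices Under ISO 81060-2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for non-invasive blood-pressure device validation studies
    following ISO 81060-2:2018 and the AAMI/ESH/ISO consensus protocol:
    derivation of the dual-observer auscultatory reference, the ordered
    exclusion cascade, accuracy criteria 1 and 2 including the
    maximum-permissible standard deviation as a function of the mean error,
    sampling-distribution audits for general and pregnant populations,
    Bland-Altman agreement analysis, observer qualification checks, and a
    configurable synthetic-study simulator so that the whole pipeline can be
    exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
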