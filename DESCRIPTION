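Package: hdcapacity
Title: Healthcare Capacity Modelling for Intrathecally Administered
    Huntington's Disease Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the healthcare resources required to deliver
    intrathecally administered disease-modifying therapies at Huntington's
    disease centres. Converts per-procedure staff and facility time into
    annual full-time-equivalent (FTE) requirements, compares them with
    interview-derived available resources per centre, classifies centres by
    component availability and patient coverage, and projects post-launch
    waiting lists with a deterministic fluid queue plus a discrete-event
    cross-check. Includes a synthetic survey generator that emulates a
    40-centre interview sample, plus JSON/CSV survey I/O and an end-to-end
    reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
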