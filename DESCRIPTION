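Package: rxsig
Title: Structured Extraction of Dosage Instructions from Free-Text Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parses free-text medication dosage instructions (prescription
    "sigs" such as "2 puffs 6 hrly prn") into a structured representation
    recording minimum and maximum dose number, dose frequency
    (administrations per interval) and dose interval (days), together with
    the dose unit and optionality markers.  The model captures variability
    and flexibility within a single prescription (ranges, "when required"
    dosing, deferred instructions), supporting drug-exposure data
    preparation for pharmacoepidemiology.  Includes a two-step rule-based
    extractor (dictionary/pattern matching followed by structuring
    meta-rules), an editable lexicon of clinical and Latin shorthand,
    accuracy evaluation against gold annotations, corpus variability
    summaries, and a template-based synthetic instruction generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    utils,
    stats,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
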