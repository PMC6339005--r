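Package: rsvpauth
Title: EEG Identity Authentication from Face RSVP Using HDCA with Genetic Channel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electroencephalogram (EEG) based identity authentication
    with a face-image rapid serial visual presentation (RSVP) paradigm. Implements
    the full pipeline: a seeded synthetic generator of event-related potential
    (ERP) recordings with self-face versus non-self-face structure; preprocessing
    (re-referencing, zero-phase Chebyshev low-pass filtering, block-average
    downsampling, epoch extraction, baseline correction, adjacent-trial
    averaging); hierarchical discriminant component analysis (HDCA) combining
    per-window Fisher linear discriminant spatial filters with logistic temporal
    fusion; genetic-algorithm channel selection maximising cross-validated HDCA
    accuracy (GA-HDCA); and a biometric evaluation protocol reporting accuracy,
    false acceptance rate and false rejection rate with stratified k-fold
    cross-validation and a permanence (retest) mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    parallel,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
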