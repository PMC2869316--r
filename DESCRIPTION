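Package: telodamage
Title: Quantification of Oxidative Guanine Damage and Telomere Integrity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification procedures for measuring oxidative guanine
    damage and integrity of mammalian telomeres. Implements
    Fpg-incision/Southern densitometric lesion estimation (mean fragment
    length as a lane centre of mass, lesions per fragment from paired
    mock/Fpg lanes, fold changes versus a control), Q-FISH telomere spot
    detection and per-chromosome-end intensity quantification with
    signal-free-end calling, CO-FISH telomere sister-chromatid-exchange
    and strand-loss event classification, two-colour G/C strand-loss
    scoring, DNA-damage-focus to telomere colocalization, and
    Table-style frequency reports with exact-test group comparisons. A
    seeded synthetic-data module generates gel lane profiles, metaphase
    images and CO-FISH signal tables with known ground truth for
    validating every step.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
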