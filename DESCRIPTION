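Package: iterscreen
Title: Machine Learning-Guided Iterative Screening for RNA-Binder Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for active-learning ("iterative") high-throughput screening
    campaigns against structured RNA targets. Covers the full path from raw
    FRET thermal-shift melt curves to melting-temperature (Tm) estimates with
    quality control, ligand-induced Tm shifts (delta-Tm) and active calls;
    a diversity-seeded, retrained-per-batch random-forest selection loop over
    fingerprint plus descriptor representations; enrichment-factor, hit-rate,
    recovery-curve, selectivity and chemotype-cluster statistics; and a
    synthetic benchmark-library generator so the whole pipeline can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
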