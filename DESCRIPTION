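Package: vsfunnel
Title: Multi-Target Consensus Virtual Screening for Broad-Spectrum MMP
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable implementation of a multi-target
    virtual-screening funnel for broad-spectrum matrix metalloproteinase
    (MMP) inhibitors. Provides a Platt-calibrated random-forest
    bioactivity filter on Morgan fingerprints, pharmacophore hypothesis
    generation (fragment-derived and ligand-based) with in-place and
    flexible 3D screening, electrostatic-potential Tanimoto similarity
    with per-target cutoff calibration, cross-target consensus hit
    selection with structural novelty clustering and PAINS flagging, and
    the percent-inhibition and single-parameter IC50 dose-response math
    used for experimental validation. Seeded synthetic-fixture
    generators supply every input the test suite needs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
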