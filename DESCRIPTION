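Package: psiscreen
Title: Percent-Spliced-In Quantification and Change Calling for
    Capillary-Electrophoresis Splicing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative splicing events from capillary
    electrophoresis RT-PCR electropherograms and calls knockdown-associated
    splicing changes. Implements DNA ladder calibration, peak detection and
    valley-to-valley integration, molar correction, assignment of detected
    peaks to expected inclusion/exclusion amplicons, percent splicing index
    (psi) computation, same-day delta-psi against mock controls, a dual-siRNA
    concordance change rule with an 8-percentage-point threshold, screen
    summaries, two-way hierarchical clustering of change profiles, and
    hypergeometric gene-set over-representation testing against GMT
    collections. A synthetic-data module generates event catalogs, ground
    truth effect tables and electropherogram traces so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
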