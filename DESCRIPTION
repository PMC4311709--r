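Package: rewetSIP
Title: Rare-Biosphere Resuscitation Analysis for Soil Rewetting SIP Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heavy-water (H2(18)O) DNA stable isotope
    probing experiments on dried and rewetted soils. Identifies labeled and
    unlabeled DNA fractions in CsTFA buoyant-density gradients, classifies
    rare-responder bacteria resuscitated by rewetting from paired dry/rewetted
    OTU tables, quantifies community turnover (rarefaction, Bray-Curtis,
    two-factor PERMANOVA), fits a lagged moisture-to-CO2 pulse regression with
    AR(1) residual correction, and converts headspace trace-gas time courses
    to net production per gram soil. A synthetic-data generator emulates the
    paired multi-ecosystem experimental design, with ground-truth labels, so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
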