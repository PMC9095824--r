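Package: paleoprov
Title: Geographic Provenance Inference for Skeletal Remains from mtDNA
    Panels and Stable Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-track provenance inference for unidentified skeletal
    remains. The genetic track calls mitochondrial haplogroups from a
    diagnostic SNP panel scored against a PhyloTree-style haplogroup tree
    (Kulczynski similarity, missing-call tolerant), aggregates calls into
    regional ancestry proportions (South Asian, West Eurasian, East
    Eurasian), compares cohorts by Fisher's exact test, and places the
    cohort among reference populations by PCA of haplogroup frequencies.
    The isotope track back-calculates drinking-water delta-18-O from tooth
    enamel carbonate, classifies samples as local or non-local against
    regional water references, and estimates C3/C4 diet fractions from
    delta-13-C by a linear mixing model. A seeded synthetic-cohort
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
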