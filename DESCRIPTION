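Package: lipidqual
Title: Lipid Nutritional Quality Analysis of Fish Fatty-Acid Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the lipid nutritional quality of fish from
    gas-chromatography fatty-acid composition tables (percent of total fatty
    acids). Parses fatty-acid labels into carbons, double bonds and omega
    series; aggregates profiles into saturated, monounsaturated and
    polyunsaturated class sums and omega-3/omega-6 sums; computes five
    nutritional quality indices (n-6/n-3 ratio, PUFA/SFA ratio, index of
    atherogenicity, index of thrombogenicity and the hypocholesterolemic/
    hypercholesterolemic ratio); classifies species by lipid content (Ackman
    categories); and runs the downstream statistical stages: Pearson
    correlation of class sums against trophic level, one-way ANOVA with Tukey
    contrasts across lipid categories, and hierarchical clustering of species
    on the standardized index matrix. Ships a 22-species Pearl River Estuary
    survey dataset as plain-text fixtures and a synthetic-profile generator
    for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
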