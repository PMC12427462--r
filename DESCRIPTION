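Package: scfptrial
Title: Microbiome and Palatability Analytics for a Feline SCFP Feeding Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a longitudinal feline feeding trial of a
    Saccharomyces cerevisiae fermentation product (SCFP). Provides readers and
    validators for shotgun-metagenome taxon count tables (Bracken-style) and
    genome annotation tables; rule-based screening of butyrate-producing
    species from genome annotations (acetyl-CoA, glutarate and 4-aminobutyrate
    routes); abundance-weighted KEGG/CAZy functional potential; compositional
    preprocessing (rare-taxon filtering, rarefaction, centered log-ratio
    transform); alpha diversity, Aitchison ordination and PERMANOVA;
    LinDA-style longitudinal differential abundance with orthogonal polynomial
    dose and time contrasts and Benjamini-Hochberg correction; two-bowl
    palatability analytics and apparent total tract digestibility. Includes a
    synthetic cohort generator emulating the trial design so that every stage
    is testable without access to the original sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
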