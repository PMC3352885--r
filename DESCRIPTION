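Package: taxocat
Title: Taxonomic Distinctness and Species-Richness Estimation from
    Linnean Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Linnean taxonomic catalogs of
    species-rich invertebrate groups.  Translates rank-based
    classifications (class, order, family, genus, species) into trees
    and computes average taxonomic distinctness (Delta+) with its
    regression on log species richness; estimates total global species
    richness from species-description time series by three routes (a
    non-homogeneous Poisson process discovery model fitted by MCMC, a
    taxonomic-productivity x-intercept regression, and ratio
    extrapolation from well-described reference faunas); and summarises
    geographic description effort with country-level regressions and a
    tropical/nontropical comparison.  Includes seeded generators for
    synthetic catalogs, description histories and country tables with
    the imbalanced allocation structure typical of understudied
    arthropod groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
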