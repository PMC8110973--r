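Package: pampachron
Title: Quantitative Biochronology of Neogene Vertebrate Faunas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordination-based temporal seriation of fossil vertebrate
    assemblages and downstream biochronological inference. Implements binary
    faunal similarity coefficients (corrected Forbes, Bray-Curtis) with NMDS,
    principal-coordinate and correspondence-analysis ordination, maximum
    likelihood appearance event ordination (AEO) with section constraints and
    taxon bootstrap, parsimony analysis of endemicity (standard and
    irreversible criteria) with symmetric resampling support, quantile
    regression age calibration of undated faunas selected by prediction
    percentage error, Foote per-capita origination and extinction rates with
    classical rarefaction, a multinomial log-likelihood statistic for faunal
    community-structure change, and 40Ar/39Ar step-heating age reduction
    (weighted-mean plateaus, York inverse isochrons, trapped-component
    correction). Includes seeded generators for synthetic faunal successions
    and step-heating spectra so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
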