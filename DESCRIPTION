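Package: ecoenz
Title: Ecoenzymatic Stoichiometry and Integrated Soil Microbiological Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated microbiological analysis of agricultural
    soils and rhizospheres. Builds carbon, nitrogen and phosphorus ecoenzyme
    pools from individual extracellular enzyme activities and summarizes them
    as stoichiometric ratios and enzymatic vectors (length and angle) that
    classify microbial nutrient limitation. Derives soil fertility indices
    (total organic carbon, molar C:N:P ratios, sum of bases, cation exchange
    capacity, base and aluminium saturation) from measured chemistry. Converts
    raw microbial enumeration observations from four methods (colony counting,
    most-probable-number maximum likelihood, total-DNA-based enumeration and
    epifluorescence microscopy) into abundances per gram of soil. Computes
    microbial biomass carbon and nitrogen from fumigation-extraction readings,
    basal respiration from alkali-trap titration, and the derived metabolic
    and microbial quotients. Integrates the standardized variables through
    principal component analysis with per-component hypothesis testing,
    k-means clustering, Spearman correlation, variance-inflation-screened
    redundancy analysis and Euclidean PERMANOVA with a dispersion check, and
    ships a seeded synthetic-data generator emulating a three-species by
    five-replicate field design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
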