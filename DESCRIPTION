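Package: sporemap
Title: Random-Spore Crossover Mapping and Tetrad Analysis for Fungal Meiosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing meiotic recombination in fungi with a
    random-spore mapping design, modelled on the genetics of the mushroom
    Coprinopsis cinerea. Calls crossovers from parental-origin genotype
    matrices of haploid spores, builds two-point genetic maps (cM, kb/cM,
    hotspot/cold/linked interval classification), compares maps between
    strains (Fisher exact, chi-square, Monte-Carlo chi-square over
    contingency tables), analyses tetrad viability distributions, and fits a
    likelihood model of meiosis I / meiosis II nondisjunction and background
    spore death. Includes a meiosis simulator (gamma-renewal crossover
    interference, obligate crossover, tetrad segregation, genotyping noise)
    for power studies and validation, an SSR fragment allele caller with a
    peak-height acceptance rule, and a gene-model component that applies
    point, splice-site, and frameshift mutations to an intron-containing gene
    and reports their protein-level effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
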