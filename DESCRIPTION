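Package: arsqtl
Title: Pedigree Heritability and QTL Linkage Analysis of Urine Arsenic
    Metabolite Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variance-component tools for family studies of arsenic
    metabolism. Computes urine arsenic species percentages (%iAs, %MMA,
    %DMA) from speciated concentrations, applies a two-stage trait
    transformation (logit, covariate adjustment under a polygenic model,
    rank-based inverse normal), estimates heritability on extended
    pedigrees by maximum likelihood with boundary-aware likelihood ratio
    tests, computes exact multipoint identity-by-descent matrices from
    short tandem repeat genotypes via an inheritance-vector hidden Markov
    model, runs genome-wide quantitative trait locus linkage scans with
    LOD scoring, and calibrates empirical LOD corrections by
    fully-informative-marker null simulation. Includes a synthetic-data
    generator producing extended pedigrees, gene-dropped microsatellite
    genotypes, and compositional arsenic phenotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
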