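Package: transgressr
Title: Quantifying Transgressive Hybrid Phenotypes Across Colour, Nanostructure,
    Genome and Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for asking whether a putative hybrid
    individual carries a transgressive phenotype, with an emphasis on
    structural (iridescent) plumage colour. Implements receptor-noise
    limited avian visual models and tetrahedral colour spaces with
    bootstrapped group colour distances; one-dimensional transfer-matrix
    optical simulation of melanosome multilayers in feather barbules;
    parent-bias and mismatch transgression metrics; Brownian-motion rates
    of colour evolution from phylogenetic independent contrasts and a
    multivariate Blomberg's K; hybrid index and interspecific
    heterozygosity from diagnostic SNPs in VCF files; and presence-only
    minimum-volume-ellipsoid niche models with Schoener's D overlap and
    background similarity tests. A synthetic-data module generates inputs
    with the statistical structure each stage assumes, so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vcfR,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
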