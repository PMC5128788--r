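Package: hilltac
Title: Hill-Number Diversity Profiles and Taxa-Accumulation Analysis for
    Amplicon Count Tables
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating bacterial diversity from OTU count tables
    with the Hill-number framework. Computes generalized diversity profiles
    (effective numbers of taxa of arbitrary order), Chao1 richness and Good's
    coverage, smoothed taxa-accumulation curves per Hill order, read-depth
    subsampling analyses with an asymptote-stability criterion, and
    maximum-likelihood fits of log-normal and Zipf taxon-abundance
    distributions with a parametric-bootstrap deviation test. Includes a
    synthetic community generator emulating hyperdiverse communities with
    heavy rare-taxon tails, mothur '.shared' and TSV table I/O, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    jsonlite,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Sequencing, Software
RoxygenNote: 7.3.3
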