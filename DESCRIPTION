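Package: ednasnp
Title: SNP Genotyping from Environmental DNA with Replicate Consensus
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-invasive SNP genotyping from environmental DNA
    (eDNA) water samples scored against tissue-derived reference genotypes.
    Provides minor-allele-frequency based panel selection, cluster-based
    genotype calling from bi-allelic fluorescence intensities stratified by
    dilution scheme, tissue-versus-eDNA concordance (call-rate) statistics,
    and a replicate-subsampling majority-vote consensus simulation that
    quantifies genotype accuracy as a function of replication level,
    extraction method and dilution -- together with a synthetic study-data
    generator so the whole pipeline runs end-to-end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
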