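Package: nodmap
Title: Mapping-by-Sequencing of EMS-Induced Nodulation Mutants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for forward-genetic dissection of
    recessive mutants by pooled backcross mapping-by-sequencing. Simulates an
    EMS-mutagenized line (G:C->A:T transition spectrum) carrying a single
    recessive causal lesion, the mutant x wild-type backcross and selfed F2
    under the Haldane map, phenotypic selection of homozygous-mutant pools, and
    pooled short-read allele counts. Analysis stages compute per-site SNP
    indexes (mutant allele frequencies), detect linkage clusters of index-1
    SNPs that localize the causal gene, annotate candidate mutations against
    gene models (splice-site, missense, nonsense, synonymous), and support
    targeted-capture panels with sibling filtering by shared EMS fingerprints,
    allelic-series grouping, and Mendelian segregation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
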