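Package: HaploPop
Title: Haplotype-Based Population Genetics and Demographic Inference for
    Mitochondrial Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for phylogeographic analysis of intraspecific
    mitochondrial (e.g. COI barcode) alignments: haplotype collapsing and
    per-region frequency tables, diversity indices (haplotype diversity,
    segregating sites, nucleotide diversity, Watterson's theta, private
    haplotypes), Tajima's D and Fu's Fs neutrality tests with
    coalescent-simulation p-values, mismatch-distribution demographic and
    spatial expansion model fitting with parametric-bootstrap
    goodness-of-fit (SSD, raggedness), distance-based AMOVA and pairwise
    Phi-ST permutation tests, statistical-parsimony haplotype networks
    with a 95 percent connection limit, molecular-clock dating of
    population expansions, and a coalescent simulator of
    bottleneck-expansion histories used for null distributions and
    parametric bootstraps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, Phylogenetics, Sequencing
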