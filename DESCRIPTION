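Package: tfsmap
Title: Mapping-by-Sequencing of Herbicide Sensitivity in Multi-Parent Cotton Populations
Version: 0.1.0
Authors@R: person("tfsmap", "maintainers", email = "tfsmap@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping-by-sequencing of a
    recessive herbicide-sensitivity locus in allotetraploid cotton. Simulates
    multi-parent advanced generation inter-cross (MAGIC) and biparental F2
    populations over a genetic map, observes genotypes under a low-coverage
    Poisson read model, applies a phenotype-concordance variant filter to
    recover a planted causal frameshift insertion, annotates coding effects
    against gene models, tests Mendelian segregation ratios, designs
    virus-induced gene silencing (VIGS) fragments by k-mer off-target
    specificity, and classifies dose-response co-expression by Pearson
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
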