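Package: allosnp
Title: SNP Array Design and Diversity Analysis for Allotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing a high-density SNP genotyping array in an
    allotetraploid crop and analysing the resulting genotype data. Implements
    a candidate-SNP filtering cascade that removes homeologous (subgenome
    divergence) artifacts, non-unique probe contexts, and ambiguous or
    multi-allelic loci; strand-specific probe scoring with
    recommendation-based tiling and genome-balanced marker selection;
    codon-level variant effect classification against gene models; genotype
    matrix quality control with polymorphism, heterozygosity and PIC
    statistics; allele-sharing distance and neighbor-joining clustering of a
    germplasm panel; and a scan for subspecies-specific high-frequency
    alleles. A synthetic-data module generates diverged subgenome pairs, gene
    models, contaminated candidate SNP pools, and structured genotype panels
    with known truth labels so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    vcfR,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
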