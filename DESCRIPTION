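Package: quartetphase
Title: Inheritance-State Analysis, Phasing, and Phased Risk Interpretation
    for Family-Quartet Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting whole-genome variant calls from a
    nuclear family quartet (father, mother, two children). Implements
    ethnicity-specific major-allele reference construction from population
    allele frequencies, a six-state inheritance-state hidden Markov model
    for Mendelian error control, sub-kilobase meiotic crossover mapping
    with Monte Carlo hotspot-enrichment testing, three-tier long-range
    haplotype phasing (pedigree, inheritance state, and population linkage
    disequilibrium), tag-SNP HLA typing, composite likelihood-ratio common
    disease risk with parental haplotype attribution, rare and synonymous
    variant prioritization (Fitch parsimony evolutionary rates, mRNA
    stability, codon usage, splice-site models), and star-allele
    pharmacogenomics including config-driven warfarin dose prediction.
    A synthetic quartet generator with known ground truth exercises every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    ape,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
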