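Package: phygst
Title: Genome Sequence Tag Analysis of Duplicated Photoreceptor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the genome sequence tag (GST)
    workflow used to inventory the phytochrome photoreceptor gene family in
    diploid and allotetraploid cottons (Gossypium spp.): degenerate-primer
    design and in-silico PCR, clone-to-contig assembly with diagnostic-SNP
    grouping and Taq-error correction, PCR-chimera screening by a
    maximal-chi-square breakpoint scan, neighbor-joining phylogenetics with
    seeded bootstrap and exhaustive parsimony, Nei-Gojobori Ka/Ks selection
    analysis with Fisher's exact tests, and synonymous-clock dating of gene
    duplications. A codon-level gene-family simulator (segmental duplication,
    A/D speciation, allopolyploid merger, purifying selection, clone sampling
    with polymerase error, amplification bias and PCR-mediated recombinants)
    provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
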