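Package: bchrom
Title: Deficiency Mapping and Sequence Analysis of a Supernumerary B Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reconstructing and characterising a supernumerary (B)
    chromosome from scaffold-level assemblies: k-mer classification of
    B-specific scaffolds against the standard (A) chromosome complement,
    deficiency mapping with panels of deletion and translocation lines
    (presence/absence matrices, consecutive-ones scaffold ordering, oriented
    pseudomolecule construction with AGP output), chromosome-arm dosage tests
    from read counts, LTR retrotransposon family clustering and insertion-age
    dating from 5'/3' LTR divergence, NG86 Ka/Ks estimation on protein-guided
    codon alignments, and nucleosome-midpoint profiling on tandem satellite
    repeats. A seeded synthetic-genome module generates every input the
    pipeline consumes, with ground truth retained for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    methods,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
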