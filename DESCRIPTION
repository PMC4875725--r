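Package: allelescope
Title: Amplicon Allele Validation and Diversity Analysis for MHC Class II Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validation and evolutionary analysis of major histocompatibility
    complex (MHC) class II beta exon 2 amplicon data from multigene families.
    Implements stepwise allele-validation filters for pooled amplicon
    sequencing (degenerate-primer matching, MID-tag demultiplexing,
    replicate- and coverage-based filtering) and for cloned Sanger reads;
    cross-species allele cataloguing with minimum-locus and pseudoallele
    inference; peptide-binding-region partitioned nucleotide (Kimura
    2-parameter) and amino-acid (Poisson-corrected) diversity with bootstrap
    standard errors; codon-level Nei-Gojobori dN/dS distances with
    Jukes-Cantor correction; neighbor-joining trees with bootstrap support;
    and a diagnostic contrasting trans-species polymorphism with convergent
    evolution. A coalescent-free simulator generates multispecies,
    multilocus genotypes and noisy amplicon or clone read sets so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
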