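Package: spsevo
Title: Evolutionary Analysis of Selenophosphate Synthetase Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the evolutionary history of selenophosphate
    synthetase (SPS/SelD) genes and, through them, of selenium utilization.
    Classifies SPS homologs by the residue aligned to the selenocysteine
    (UGA-encoded) site of a seed profile, infers Sec and selenouridine traits
    from genome marker tables with an exact co-occurrence test, detects
    terminal extensions and gene fusions, quantifies per-branch Ka/Ks after
    duplication via codon-level parsimony ancestral reconstruction and
    Nei-Gojobori counting, scans coding sequence around in-frame UGA codons
    for readthrough signals (the GGG-UG[C/U] hexanucleotide and SRE/HRE
    stem-loops found by dynamic-programming folding), and labels gene-tree
    duplications to emit site-substitution event histories. A synthetic-data
    generator plants all of these signals with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
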