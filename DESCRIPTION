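Package: askpoly
Title: Polymorphism and Selection Analysis of the Arabidopsis Skp1-Like Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for polymorphism and molecular-evolution analysis
    of a multigene family across natural accessions. Assembles per-accession
    allelic sequences from quality-filtered SNP calls, computes per-region
    diversity statistics (segregating sites, nucleotide diversity, Watterson's
    theta, Tajima's D, minor-allele-frequency spectra), runs sliding-window
    diversity scans with latitude- or expression-based group comparisons,
    performs a pairwise codon-model (GY94) likelihood-ratio test of neutral
    evolution with a Nei-Gojobori counting cross-check, annotates tandem
    duplications and intron counts from gene models, and clusters genes by
    their polymorphism profiles. A built-in coalescent and codon-evolution
    simulator provides inputs with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
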