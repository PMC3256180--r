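Package: nbsdecon
Title: Deconstructing Paleopolyploid Genomes from NBS Resistance-Gene Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect an ancient polyploid plant genome into its
    component genomes using the organization of nucleotide-binding-site
    resistance (NBS-R) genes. Implements distance-based tandem-duplication
    cluster calling, protein-guided codon alignment with Nei-Gojobori (NG86)
    synonymous-divergence (Ks) estimation, averaged between-cluster similarity
    scoring with percentile thresholding and graph-based chromosome grouping,
    detection of residual helitron transposition footprints (CTAG signature
    plus inverted-repeat stem-loop) in gene 3' regions, molecular-clock dating
    of transposition and cluster-formation events, chromosome-triplet
    compatibility analysis, and a synthetic-genome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
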