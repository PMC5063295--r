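Package: triohet
Title: Genic-SSR Mining and Trio SNP Zygosity Analysis for Transcriptome
    Marker Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing molecular markers from assembled plant
    transcriptomes, modelled on a parent/parent/F1-hybrid study design.
    Mines perfect microsatellites (SSRs) from unigene sets under
    MISA-style reiteration thresholds, canonicalizes repeat motifs,
    classifies loci as Type I/II, and designs flanking PCR primer pairs
    under hard length/product/GC/clamp constraints. Builds per-variety
    base pileups from variety-tagged read alignments, calls biallelic
    SNPs under stringent depth and base-quality filters, classifies
    parent/parent/hybrid trios into eight zygosity classes and derives
    per-variety heterozygosity summaries (novel, maintained and lost
    heterozygosity in the hybrid). A seeded simulator generates
    reference transcripts with embedded SSRs, diploid trio genotypes in
    configurable class proportions (direct or Mendelian mode), and
    error-bearing reads with truth tables, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
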