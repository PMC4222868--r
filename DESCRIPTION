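Package: BidiProm
Title: Discovery and Annotation of Plant Bidirectional Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide discovery of putative bidirectional promoters in
    compact plant genomes: identifies divergent (head-to-head) gene pairs
    whose transcription start sites lie within a configurable window
    (default 100-600 bp), extracts the shared intergenic region, scans it
    for abscisic-acid-responsive cis-elements (G-box CACGTG, DRE/CRT CCGAC,
    CE3 coupling elements) with full IUPAC degeneracy and strand handling,
    and assembles a candidate table with element counts and flags. Includes
    a binomial background model for motif depletion, Mendelian transmission
    calculators for T-DNA insertion genetics, and a seed-deterministic
    synthetic genome generator with ground-truth manifests for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
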