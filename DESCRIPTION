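Package: svforensics
Title: Forensics of Structural-Variant Junctions, Chromothripsis Statistics
    and Fusion-Transcript Concordance in Chaotic Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect heavily rearranged tumor genomes such as
    osteosarcoma. Measures junction microhomology at structural-variant
    breakpoints and compares category profiles (none, 1-5 bp, 6-25 bp)
    against a random-genome background with a Monte-Carlo Fisher test;
    tests per-chromosome breakpoint clustering against an exponential
    inter-breakpoint null (chromothripsis inference) together with
    join-orientation randomness and coverage fold-change (MMBIR-like
    amplification); estimates structural-variant allele fractions from
    spanning, split and concordant read counts; runs the fusion-transcript
    filter cascade (read support, normal-tissue panel, junction sequence
    complexity) and matches chimeric transcripts to underlying genomic
    rearrangements, distinguishing direct fusions, read-through events and
    trans-splicing; summarizes gene-centric aberration cohorts (class
    frequencies, intron hotspots, protein-domain consequences, wild-type
    allele statistics); and quantifies radiation-induced p53 target
    induction with the 2^-ddCt method. A synthetic-genome simulator plants
    rearrangements with controlled microhomology, clustering, allele
    fraction, coverage amplification and fusion provenance so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
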