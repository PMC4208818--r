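Package: iqdfam
Title: Genome-Wide Analysis of Plant IQ67-Domain (IQD) Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide characterization of
    the plant-specific IQ67-domain (IQD) family of calmodulin-binding
    proteins, modelled on the soybean (Glycine max) GmIQD1-67 family.
    Detects IQ, 1-5-10 and 1-8-14 calmodulin-recruitment motifs and calls
    complete IQ67 domains from a motif grammar; analyses exon/intron
    organization and intron phases, including the diagnostic phase-0 intron
    between IQ67-domain codons 16 and 17; classifies duplicate gene pairs as
    tandem, segmental or other; estimates Ka/Ks by the Nei-Gojobori (1986)
    method with Jukes-Cantor correction and dates duplications from Ks;
    detects microsynteny blocks around anchor genes and scores synteny
    quality; builds neighbor-joining trees with bootstrap support; and
    quantifies expression by RPKM normalization, Pearson/complete-linkage
    clustering and qPCR 2^-ddCt fold changes. A synthetic-data generator
    produces genomes, gene families, duplicates, expression matrices and CT
    tables with known ground truth so that every stage is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
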