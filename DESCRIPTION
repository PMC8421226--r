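Package: pregbs
Title: Evolutionary Analysis of CpG-Deamination-Derived Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to trace transcription factor binding sites that arose by
    deamination of methylated CpG dinucleotides, built around the degenerate
    glucocorticoid receptor (GR) core motif GnACAnnnTGTnC. The package scans
    genomes for degenerate IUPAC motifs on both strands, projects human motif
    occurrences through pairwise whole-genome alignments (MAF) to extract
    gapless homologous 13-mers, classifies single-base variants at the two
    CpG-informative motif positions with strand folding, labels occurrences
    as regulatory by interval overlap with annotation tracks (BED), and
    applies the accompanying exact statistics (chi-square goodness of fit,
    one-sided Fisher test, hypergeometric overlap tail). A self-contained
    genome-evolution simulator with CpG-hypermutable substitutions, optional
    indels, ground-truth alignments and regulatory tracks makes the whole
    pipeline testable without genome downloads, and a one-site saturation
    binding module fits fluorescence-polarization titrations (Kd with
    bootstrap confidence intervals).
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
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
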