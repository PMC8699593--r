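Package: argskew
Title: Arginine Codon Substitution Spectra and Skew Detection in Somatic Mutation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for codon-level analysis of somatic point mutations, with
    arginine as the worked instance. Enumerates and classifies the single
    nucleotide substitution space of any codon family, annotates genomic
    point mutations to codon-level events using a local reference FASTA and
    GFF3 gene model (strand- and phase-aware, including intron-split codons),
    computes 12-category base-change spectra, strand-specific transition
    frequencies, per-codon mutation shares versus genome codon usage, and
    amino-acid-by-source-codon substitution tables with coding, silent and
    noncoding controls, and detects genes with a skewed arginine substitution
    bias. Includes a fully seeded synthetic mutation simulator (reference,
    gene models and a COSMIC-like mutation table with a ground-truth
    manifest) so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
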