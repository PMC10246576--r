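Package: gintervals
Title: Genomic Interval Algebra and Bioinformatic File Formats on a
    Persistent Interval Tree
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Operations with genomic intervals bounded by an assembled
    genome (searching, intersecting, merging, subtracting, complement)
    implemented on an immutable red-black interval tree, together with
    stream-based readers and writers for the BED, GFF3, GTF, WIG, VCF,
    SAM, BAM (BGZF), FASTA and FASTQ formats, analysis helpers for
    breadth of coverage and transition/transversion summaries, a
    command-line interface, and a seeded property-based validation
    harness built on lossless round-trip guarantees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
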