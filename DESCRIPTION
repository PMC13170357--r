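Package: tnbarseq
Title: Mapping Barcoded T-DNA Insertions and Temperature-Dependent Mutant
    Fitness from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for randomly barcoded insertional mutagenesis screens in
    fungi. Maps T-DNA/genome junction reads to a reference genome to build an
    annotated insertion pool file (junction detection with mismatch tolerance,
    seed-and-extend ungapped local alignment with bitscore/E-value filters,
    uniqueness resolution, Hamming-1 barcode error collapsing, near-position
    resolution, insertion classification and gene assignment), counts barcodes
    from BarSeq amplicon reads with total-count normalization, and computes
    per-gene temperature-dependent fitness as baseline-normalized log2 ratios
    with one-sample Wilcoxon signed-rank or Mann-Whitney U tests and
    Benjamini-Hochberg FDR control. Includes a synthetic-data generator
    (genomes, annotations, insertion truth sets, junction reads, barcode count
    tables with planted effects) so the whole pipeline can be exercised and
    calibrated without external data.
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
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
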