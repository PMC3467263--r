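Package: ir1screen
Title: Cross-Species Screen for IR1-Type Nuclear Receptor Response Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery screen for farnesoid X receptor (FXR) response elements
    of the IR1 type (inverted repeat of two hexamer half-sites with a 1 bp
    spacer) and related repeat geometries. Compiles degenerate half-site
    consensus patterns into full-site matchers, scans sequence under a
    mismatch budget on either strand, extracts gene-anchored windows
    (-20,000 bp to +10,000 bp around the first-exon 5' end) from FASTA/GFF3,
    intersects per-species hit tables over ortholog groups to call conserved
    candidate target genes, and generates multi-species synthetic genomes
    with elements planted at known gene-relative offsets for validation.
    Also implements the accompanying assay quantifications: delta-delta-Ct
    relative expression, relative luciferase activity and fold induction,
    in-silico PCR product sizing, and the unpaired t-test with significance
    stars.
License: MIT
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
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
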