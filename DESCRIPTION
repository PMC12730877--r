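Package: cubtools
Title: Genome-Wide Codon Usage Bias Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide codon usage bias (CUB) analysis of coding
    sequence (CDS) collections: CDS quality filtering (length, frame, internal
    stops, start/stop codons), amino-acid composition, relative synonymous
    codon usage (RSCU), positional GC content, Wright's effective number of
    codons (ENC), neutrality-plot mutation-selection decomposition, expected
    ENC versus GC3 curves with per-gene selection calls (dNCsg, dNC),
    group-level nonparametric comparisons, phylogenetically independent
    contrasts, Euclidean profile clustering, hypergeometric term enrichment,
    and a synthetic multi-genome CDS simulator with controllable mutational
    GC3 bias and codon-level selection for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
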