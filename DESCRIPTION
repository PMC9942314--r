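Package: refix
Title: Targeted Re-Alignment of Short Reads Around Reference Genome Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects short-read alignments over falsely duplicated and
    collapsed regions of a reference genome. Falsely duplicated regions carry
    an extra, near-identical copy of a locus that splits reads across copies,
    depressing coverage and mapping quality; collapsed regions merge two real
    paralogs into a single reference copy, inflating coverage and producing
    spurious heterozygous calls at paralogous sequence variants. The package
    builds a patched reference (hard-masked extra copies plus appended decoy
    contigs), extracts affected read pairs from an existing coordinate-sorted
    BAM, re-aligns them with a pluggable backend (including a built-in
    deterministic seed-and-extend paired-end mapper), and optionally splices
    the corrected records back into a genome-wide BAM. Region-level
    diagnostics (mapping-quality summaries, depth ratios, per-site inbreeding
    coefficients), a desk-scale pileup genotyper, a truth-VCF benchmarking
    comparator, and a simulator of both reference-error classes make the full
    workflow testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
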