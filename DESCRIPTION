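Package: diplosv
Title: Haplotype-Resolved Assembly-Based Structural Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects structural variants (insertions, deletions, inversions,
    translocations and duplications) and small indels from haplotype-resolved
    contig-to-reference alignments. Unphased long reads are attributed to the
    haplotype of a phase block by unique k-mer fingerprint similarity with an
    empirical-quantile significance test; split-alignment and CIGAR signatures
    are clustered within and across haplotypes, genotyped, filtered with
    read-alignment evidence, de-duplicated by one-to-K clustering, and written
    as a phased VCF. Ships a synthetic diploid fixture generator (implanted
    variants, phase blocks, error-bearing simulated reads) and a minimal
    Truvari-style evaluator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
SystemRequirements: minimap2, samtools (only for the alignment-backed
    pipeline steps; all formula-level operations run without them)
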