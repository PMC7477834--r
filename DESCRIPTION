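Package: svsigcall
Title: Structural Variant Discovery and Genotyping from Long-Read Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes structural variants (deletions, insertions,
    duplications, inversions and translocation breakends) from coordinate-sorted
    long-read alignments. SV evidence is collected per read as signatures, both
    from large insertion/deletion CIGAR operations (with heuristic merging of
    fragmented indels) and from the geometry of split alignments. Signatures are
    clustered by genomic position, refined into allele-specific sub-clusters by
    an adaptive length tolerance, and converted into genotyped VCF records under
    a bi-allelic likelihood model. The package also ships a synthetic-alignment
    fixture generator that implants SVs into a toy reference and emits SAM
    records emulating aligner behaviour around each SV type, and a benchmarking
    module implementing breakpoint/breakend matching, precision/recall/F1,
    genotype-aware statistics, trio recall and Mendelian discordance rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
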