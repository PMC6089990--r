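Package: conseqr
Title: CDS Consequence Annotation and Strain Comparison for Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-strain variant calls into codon-level coding-sequence
    consequences for comparative genomics of mutagenized yeast strains.
    Classifies substitutions as synonymous, missense (split into conservative
    and non-conservative by BLOSUM62 score), nonsense (stop-gain), sense
    (stop-loss) or start-loss, and indels as frameshift or in-frame; computes
    the variants that distinguish a mutant from its parent strain; flags
    CDS-inactivating lesions under a configurable policy; applies fold-change
    plus t-test thresholds to replicated expression matrices with gene-set
    overlap arithmetic; tests spore and tetrad segregation data against
    Mendelian monogenic expectations; and simulates toy genomes, NTG-like
    mutagenesis with ground-truth labels, and planted-effect expression data
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    tools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
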