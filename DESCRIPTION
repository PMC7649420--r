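Package: srnaqtl
Title: Reference-Free Small-RNA Expression QTL Mapping in Immortalized F2
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a quantify-then-align workflow for genetic dissection
    of small-RNA (sRNA) expression. Unique sRNA sequences and greedily
    assembled sRNA clusters are quantified per individual without a reference
    genome (reads-per-million and median-of-ratios normalization), expression
    traits are scanned for QTL across a recombination-bin genetic map with
    composite-interval-mapping-style cofactors and permutation thresholds,
    trait sequences are then aligned to the two parental genomes to resolve
    each QTL as local or distant and to authenticate multi-mapped alignments,
    QTL hotspots are called, and long inverted repeats (hairpin-RNA precursor
    candidates) are detected and associated with sRNA expression. A synthetic
    population generator (parental genomes with planted inverted repeats,
    recombinant inbred lines, paired-cross immortalized F2s, negative-binomial
    sRNA libraries and mRNA reads) makes the whole pipeline testable
    end-to-end with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
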