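Package: divProfiler
Title: Intragenomic Variant Profiling of Multicopy ITS2 Amplicons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resolves Symbiodiniaceae taxa from paired-end ITS2 amplicon
    sequencing by exploiting the intragenomic diversity of the multicopy
    rDNA marker. Implements a standardised quality-control chain (read-pair
    merging, ambiguity and homopolymer screening, clade separation against
    nine reference sequences, abundance filtering, primer trimming, length
    screening and an entropy-based decomposition of unique sequences),
    discovers re-occurring sets of defining intragenomic variants (DIVs)
    across samples to delineate ITS2 type profiles, characterises profiles
    by DIV relative-abundance ranges, and assigns profiles to samples with
    support for mixed within- and between-genus symbiont communities.
    Between-sample and between-profile Bray-Curtis and weighted UniFrac
    distances with principal coordinate ordination, a 97-percent-similarity
    OTU clustering baseline, count-table and FASTA outputs, a local analysis
    store, and a ground-truthed synthetic community simulator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
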