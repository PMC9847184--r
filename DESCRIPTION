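Package: melonprint
Title: Perfect SSR/SNP Marker Panels, DNA Fingerprinting and Population
    Analysis for Crop Variety Identification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and exploiting "perfect" molecular marker
    panels for crop variety identification, developed around melon (Cucumis
    melo) variety fingerprinting. Scans a genome for microsatellite (SSR)
    tracts and screens SSR and SNP candidates against a multi-sample variant
    catalog for clean, uniquely mappable flanking sequence; stores variety
    fingerprints in a SummarizedExperiment-derived genotype matrix with
    per-locus diversity statistics (PIC, heterozygosity, missing rate);
    counts pairwise marker differences between varieties and selects minimal
    core marker sets by greedy set cover with an exhaustive oracle; computes
    Bruvo's microsatellite distance, neighbor-joining trees, three-level
    AMOVA and Weir-Cockerham Fst; and scans per-population SNP-index in
    sliding windows to find subspecies-diagnostic markers. A seeded synthetic
    data generator emulates a two-subspecies variety panel so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
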