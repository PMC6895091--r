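Package: nucsnp
Title: Nucleosome Occupancy and Chromatin-State Annotation at Variant Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A variant-centric MNase-seq analysis pipeline: transforms aligned
    single-end reads into dyad-centred nucleosome occupancy tracks, computes
    averaged occupancy profiles around anchor sites (TSSs, SNPs), tests
    per-variant nucleosome occupancy with a Poisson enrichment model and
    combines calls across cell types, annotates variants against histone-mark
    peak sets with bivalent chromatin-state classification, and scores
    reference/alternate allele effects on transcription-factor motifs.
    Includes a synthetic-data generator emulating the canonical promoter
    nucleosome architecture (NDR flanked by positioned -1/+1 nucleosomes and a
    phased downstream array) so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
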