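Package: arfkit
Title: Characterization Toolkit for Auxin Response Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Plant Genomics", "Toolkit Authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide characterization of the
    Auxin Response Factor (ARF) transcription-factor family, built around the
    chickpea (Cicer arietinum) family as a worked reference set. Covers
    family-table genomics (chromosomal distribution, isoform census, tandem
    cluster detection), duplication dating from Ka/Ks with selection-mode
    calling, protein physicochemistry (Bjellqvist isoelectric point, average
    molecular weight) and domain-architecture/middle-region classification into
    activators and repressors, distance-based phylogeny (Poisson-corrected
    distances, neighbor joining, bootstrap supports, sister pairs), promoter
    cis-regulatory element scanning with a GC background model and Monte-Carlo
    enrichment p-values, RT-qPCR normalization (amplification efficiency, geNorm
    M, qBase CV, multi-reference NRQ with error propagation, 3':5' integrity
    QC), expression-matrix ordination and clustering, and seeded synthetic-data
    generators so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
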