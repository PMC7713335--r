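Package: splicemark
Title: Proteogenomic Discovery of Alternative Splicing Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A proteogenomic workflow for discovering alternative-splicing
    biomarkers from paired RNA-Seq and mass-spectrometry cohorts. Splice
    junction observations are annotated against a transcript model by
    block-to-region overlap rates and classified into six alternative
    splicing categories (single exon, single intron, intron retention
    junctions, normal and exon-skipping junctions); events differentially
    present between two sample groups are selected by chi-square testing
    with Storey-Tibshirani q-values; selected events are converted into a
    customized junction-peptide FASTA database (120-nt flanks, phase-based
    or three-frame translation keeping the longest peptide) with a reversed
    decoy companion; and peptide-spectrum matches from an external search
    engine are filtered by target-decoy FDR, E-value, and a final
    significance plus minimum-hit rule to yield peptide biomarkers. A seeded
    simulator generates toy genomes, junction observations, and PSM tables
    with planted differential events so the full pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
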