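Package: seedmir
Title: Seed Small-RNA miRNAome Discovery and Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for characterising the miRNA
    transcriptome of plant seed small-RNA libraries without a reference
    genome. Raw reads are quality-filtered, adapter-trimmed and collapsed
    into unique 18-25 nt tags; tags are classified against non-coding and
    organellar RNA references and matched exactly to known plant mature
    miRNAs with family grouping; novel pre-miRNA hairpins are discovered on
    assembled transcript contigs via block-anchored read patterns, RNAfold
    secondary structure, MFE/MFEI thresholds and 5p/3p mature-star pairing
    with isomiR cataloguing; per-miRNA abundance is TMM-normalised and
    tested for differential abundance with a negative-binomial exact test
    and the Audic-Claverie test jointly; and miRNA targets are predicted on
    contigs with a complementarity expectation score. A seeded synthetic
    data generator produces ground-truthed libraries, contigs with planted
    hairpin precursors and reference sets so the whole pipeline can be
    exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold on the PATH)
Config/testthat/edition: 3
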