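Package: FusionChip
Title: Multiplex RT-PCR and Microarray Screening of Leukemia Fusion Transcripts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models a chimeric-primer multiplex RT-PCR plus oligonucleotide
    microarray panel for screening the fifteen chromosomal translocations most
    frequently observed in acute and chronic leukemia (AML1-ETO, PML-RARA and
    its variant rearrangements, CBFB-MYH11, MLL rearrangements, TEL-AML1,
    E2A-PBX1, BCR-ABL p190/p210/p230, SIL-TAL1). Provides a typed panel of
    tagged primers, junction and partner probes and array layout; an in-silico
    simulator of reverse transcription, two-round universally tagged PCR,
    biotin labeling and probe hybridization; a synthetic fixture generator for
    pseudo-transcripts and noisy spot-intensity grids; the spot-intensity
    decision procedure (replicate averaging, per-probe background and
    biotin-referenced cutoff thresholds, fusion call rules with splice-variant
    labels and internal-control QC); and cohort summaries with per-group
    translocation frequencies, splice-variant distributions and concordance
    against reference diagnoses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, SequenceMatching, Microarray, Classification
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'panel.R'
    'assay.R'
    'fixtures.R'
    'caller.R'
    'cohort.R'
    'cohort-compositions.R'
    'io.R'
    'FusionChip-package.R'
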