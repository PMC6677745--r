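Package: pouchrom
Title: Chromatin Binding Trajectories and Opening Attribution for POU Factor
    Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor occupancy and
    chromatin accessibility during somatic cell reprogramming driven by POU
    factors (Oct4, Oct6 and the Sox2-heterodimerization-deficient Oct4
    mutant). Provides binary occupancy-trajectory classification of merged
    ChIP-seq summits across time points, position-weight-matrix scanning and
    per-locus annotation of POU motif classes (octamer, SoxOct, MORE,
    MORE+1), accessibility tiering and open/closed chromatin trajectory
    calls from ATAC-seq, attribution of chromatin opening to Sox2/POU
    co-binding with rank-sum statistics, motif-accessibility deviation
    scores, STARR-seq consensus enhancer calling, and a fully deterministic
    synthetic-data generator with a machine-readable truth table that
    emulates the dimerization-driven binding rules and a logistic chromatin
    opening model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
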