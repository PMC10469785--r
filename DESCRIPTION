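Package: bpdesign
Title: Design and In-Silico Evaluation of Elongation-Arrest Blocking Primers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, validating and evaluating elongation-arrest
    blocking primers (3' C3-spacer oligos) that suppress host amplification in
    marker-gene metabarcoding libraries such as the 18S rRNA V9 region.
    Provides degeneracy-aware (IUPAC) sequence matching, in-silico PCR with
    degenerate primers, exhaustive candidate-window enumeration inside the
    amplicon interior, host-uniqueness and off-target mismatch screening,
    rule-based validation of externally supplied blocking oligos, and a
    deterministic mock-community simulator that predicts per-template
    amplified/blocked outcomes and community-level host suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
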