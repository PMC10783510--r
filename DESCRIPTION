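Package: g4switch
Title: G-Quadruplex/Hairpin Switch Prediction for G/C-Rich DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores, detects and classifies G/C-rich DNA sequences that can
    switch between a G-quadruplex and a hairpin depending on the sodium/
    potassium balance. Implements base-wise G4Hunter scoring with the classic
    run-length penalty and softened per-cytosine penalties for C-runs,
    detection of putative quadruplex sequences of four motif classes
    (classical, long-loop, bulged, G-vacancy), cytosine-run decomposition and
    the N statistic, maximal intramolecular G-C base pairing by a
    Nussinov-style dynamic program with dot-bracket traceback, and a
    rule-based three-regime phase classification (G4-locked, switchable,
    hairpin-locked) with a potassium threshold prediction for named
    sodium/potassium buffers. Ships the CEB25 oligonucleotide mutant family
    and a deterministic planted-motif synthetic genome generator, plus a
    command-line interface producing TSV and BED output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
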