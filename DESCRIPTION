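Package: jointmotif
Title: Joint-Motif Precision-Recall Analysis of Transcription Factor
    Binding Motif Pairs in ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects mutually exclusive occurrence of pairs of
    transcription-factor binding-site motifs in ChIP-seq peak sets.
    Motif recognition thresholds are calibrated on a reference
    (promoter) sequence set to a common expected-recognition-rate (ERR)
    scale, so that heterogeneous motif models (position weight matrices
    and external precomputed-score models) become comparable.  For each
    single motif and for the "joint" motif (recognized when at least one
    of the two singles is recognized) the package builds corrected
    precision-recall curves truncated at a maximal expected frequency
    ERRMAX, computes the baseline-subtracted partial area pAUPRC and
    the ratio of areas RAUC; RAUC > 1 flags motif pairs that segregate
    into different peaks.  Includes application modes for single pairs,
    all pairs of a collection, one motif against a collection, and the
    top-scoring subset of a collection, plus a synthetic-data generator
    for benchmark peak sets with motifs implanted under independent,
    co-occurring and mutually exclusive regimes, with G/C-matched
    negative sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
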