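Package: txunify
Title: Unified Sequence Model of Transcription Initiation and Termination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores every base of a genome for transcription-initiation and
    cleavage/polyadenylation (CPA) potential on both strands using binned
    sequence-feature classifiers (Random Forests over motif, base-content and
    poly(dA:dT) features), and integrates the four resulting score tracks with
    an eight-state strand-symmetric hidden Markov model that outputs per-base
    posterior probabilities of transcript structure (TSS, transcript body,
    CPA site, bidirectional terminator, intergenic). Includes fine-mapping of
    exact start and cleavage bases from initiator (CA) and cleavage ([G/C]AA)
    micro-motifs, a synthetic-genome simulator with implanted promoter and
    terminator grammars for end-to-end validation, combinatorial
    promoter-library design, sort-seq expression estimation, and the
    evaluation metrics used to assess genome segmentation (AUROC,
    tolerance-aware per-base precision/recall, transcript-level matching,
    strand cross-correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    glmnet,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
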